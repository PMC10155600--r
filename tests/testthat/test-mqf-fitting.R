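truth_58 <- mqf_params(C0 = 1, C1 = 1, nu_eff = 188, R2fast = 153, R2slow = 46)

test_that("noiseless curves are recovered to near machine precision", {
  g <- tau_grid()
  dq <- generate_buildup_curve(truth_58, g, "DQF_MA", snr = Inf, seed = 1)
  f <- fit_dqf(dq)
  expect_identical(f$status, "ok")
  expect_equal(unname(f$params[["nu_eff"]]), 188, tolerance = 1e-6)
  expect_equal(unname(f$params[["R2fast"]]), 153, tolerance = 1e-6)
  expect_equal(unname(f$params[["C0"]]), 1, tolerance = 1e-6)

  tq <- generate_buildup_curve(truth_58, g, "TQF", snr = Inf, seed = 1)
  ft <- fit_tqf_constrained(tq, f)
  expect_equal(unname(ft$params[["R2slow"]]), 46, tolerance = 1e-6)
  expect_equal(unname(ft$params[["C1"]]), 1, tolerance = 1e-6)
})

test_that("optimizer matches the exhaustive grid-search oracle on noiseless instances", {
  g <- tau_grid()
  set.seed(42)
  for (i in 1:4) {
    p <- mqf_params(C0 = runif(1, 0.5, 2), nu_eff = runif(1, 60, 300),
                    R2fast = runif(1, 40, 250))
    cv <- generate_buildup_curve(p, g, "DQF_MA", snr = Inf, seed = i)
    f <- fit_dqf(cv)
    ora <- oracle_dqf_grid(cv$tau, cv$amplitude)
    expect_lt(abs(f$params[["nu_eff"]] - ora$nu_eff), 1 + 1e-9)
    expect_lt(abs(f$params[["R2fast"]] - ora$R2fast), 1 + 1e-9)
  }
})

test_that("constrained TQF fit agrees with the 1-D profiled scan oracle", {
  g <- tau_grid()
  cv <- generate_buildup_curve(truth_58, g, "TQF", snr = 30, seed = 7)
  ft <- fit_tqf_constrained(cv, c(nu_eff = 188, R2fast = 153))
  ora <- oracle_tqf_scan(cv$tau, cv$amplitude, 188, 153)
  expect_lt(abs(ft$params[["R2slow"]] - ora$R2slow), 0.1 + 1e-9)
})

test_that("the sequential order is enforced and frozen parameters are never re-estimated", {
  g <- tau_grid()
  tq <- generate_buildup_curve(truth_58, g, "TQF", snr = 20, seed = 3)
  # no companion fit: refuses
  failed <- fit_dqf(generate_buildup_curve(
    mqf_params(C0 = 0, nu_eff = 0, R2fast = 1), g, "DQF_MA", snr = Inf, seed = 1))
  expect_error(fit_tqf_constrained(tq, failed), "sequential")
  # frozen values pass through unchanged
  ft <- fit_tqf_constrained(tq, c(nu_eff = 170, R2fast = 140))
  expect_identical(unname(ft$fixed), c(170, 140))
  expect_named(ft$params, c("C1", "R2slow"))
})

test_that("SNR-based standard errors match Monte-Carlo spread and vanish at zero noise", {
  g <- tau_grid()
  # sigma = 0: all SEs zero
  dq0 <- generate_buildup_curve(truth_58, g, "DQF_MA", snr = Inf, seed = 1)
  f0 <- fit_dqf(dq0)
  expect_true(all(f0$se == 0))

  # SE from one fit tracks the empirical spread over 200 repeats within 15%
  st <- mqf_recovery_study(truth_58, n_seeds = 200, snr = 20)
  dq <- generate_buildup_curve(truth_58, g, "DQF_MA", snr = 20, seed = 400)
  f <- fit_dqf(dq)
  expect_lt(abs(f$se[["nu_eff"]] / st$sd[["nu_eff_Hz"]] - 1), 0.15)
  expect_lt(abs(f$se[["R2fast"]] / st$sd[["R2fast_per_s"]] - 1), 0.15)
  # relative coupling uncertainty sits at the few-percent scale seen in the
  # reference shear series (188 +/- 6)
  expect_lt(f$se[["nu_eff"]] / f$params[["nu_eff"]], 0.05)
})

test_that("presence detection separates signal from no-shear / high-temperature nulls", {
  g <- tau_grid()
  # clear signal
  sig <- generate_buildup_curve(truth_58, g, "DQF_MA", snr = 20, seed = 2)
  expect_true(detect_mqf_presence(sig)$signal)
  # no-shear condition at 288 K: zero coupling, amplitude-referenced noise
  hc <- helix_coil_model()
  tab <- generate_mqf_condition_table(hc, 288, c(0))
  p0 <- mqf_params(C0 = tab$C0, C1 = tab$C1, nu_eff = tab$nu_eff_Hz,
                   R2fast = tab$R2fast_per_s, R2slow = tab$R2slow_per_s)
  hits <- vapply(1:20, function(s) {
    dq <- generate_buildup_curve(p0, g, "DQF_MA", snr = 20, seed = s)
    tq <- generate_buildup_curve(p0, g, "TQF", snr = 20, seed = 1000 + s)
    detect_mqf_presence(dq)$signal || detect_mqf_presence(tq)$signal
  }, logical(1))
  expect_lte(mean(hits), 0.1)
})

test_that("shear-dependence regression equals the closed-form normal equations", {
  sh <- kc_mqf_shear_series()
  df <- data.frame(shear_rate_per_s = sh$shear_rate_per_s,
                   nu_eff_Hz = sh$nu_eff_Hz, nu_eff_se_Hz = sh$nu_eff_se_Hz,
                   R2slow_per_s = sh$R2slow_per_s,
                   R2slow_se_per_s = sh$R2slow_se_per_s)
  fit <- fit_shear_dependence(df)
  ora <- oracle_linreg(df$shear_rate_per_s, df$nu_eff_Hz, 1 / df$nu_eff_se_Hz^2)
  expect_equal(fit$nu_slope, ora$slope, tolerance = 1e-9)
  expect_equal(fit$nu_intercept, ora$intercept, tolerance = 1e-9)
  # the slow rate is shear-independent: flatness not rejected at 5%
  expect_gt(fit$r2slow_flatness_p, 0.05)
  # a constant coupling series gives slope 0
  flat <- data.frame(shear_rate_per_s = c(10, 20, 40, 80), nu_eff_Hz = 100,
                     R2slow_per_s = c(46, 50, 44, 51))
  # exact data: summary.lm's perfect-fit warning is expected here
  expect_equal(suppressWarnings(fit_shear_dependence(flat)$nu_slope), 0,
               tolerance = 1e-12)
  expect_error(fit_shear_dependence(df[1:2, ]), ">= 3")
})

test_that("Arrhenius fits are exact on exact data and reproduce the reference trends", {
  # exact T2(T) = A exp(-B/T): slope -B recovered to 1e-9 relative
  Tk <- c(288, 291, 295, 298)
  A <- 0.02; B <- 1500
  df <- data.frame(temperature_K = Tk,
                   R2fast_per_s = 1 / (A * exp(-B / Tk)),
                   R2slow_per_s = 1 / (0.01 * exp(-700 / Tk)),
                   nu_eff_Hz = 5e6 * exp(-3000 / Tk))
  ar <- suppressWarnings(arrhenius_analysis(df))  # exact data: perfect-fit warning
  expect_equal(ar$ln_T2fast$slope, -B, tolerance = 1e-9)
  expect_equal(ar$ln_T2slow$slope, -700, tolerance = 1e-9)
  expect_equal(ar$ln_nu_eff$slope, -3000, tolerance = 1e-9)
  expect_true(all(ar$ln_T2fast$points$within_band))

  # reference temperature series: ln T2fast vs 1/T has negative slope and
  # matches the closed-form normal equations
  te <- kc_mqf_temperature_series()
  te <- te[te$signal, ]
  ar2 <- arrhenius_analysis(te)
  expect_lt(ar2$ln_T2fast$slope, 0)
  ora <- oracle_linreg(1 / te$temperature_K, log(1 / te$R2fast_per_s))
  expect_equal(ar2$ln_T2fast$slope, ora$slope, tolerance = 1e-9)
  expect_equal(ar2$ln_T2fast$intercept, ora$intercept, tolerance = 1e-9)
  expect_error(arrhenius_analysis(df[1:2, ]), ">= 3")
})

test_that("recovery error shrinks with increasing SNR", {
  p <- truth_58
  err <- vapply(c(10, 20, 40), function(snr) {
    st <- mqf_recovery_study(p, n_seeds = 30, snr = snr, seed_offset = 7000)
    st$sd[["nu_eff_Hz"]]
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  # roughly proportional to 1/SNR: quadrupling SNR cuts the spread ~4x
  expect_lt(err[3] / err[1], 0.5)
})
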