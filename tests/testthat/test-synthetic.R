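test_that("build-up generator is seeded, noiseless in the SNR=Inf limit, and SNR-calibrated", {
  p <- mqf_params(C0 = 1, C1 = 1, nu_eff = 142, R2fast = 145, R2slow = 52)
  g <- tau_grid()

  a <- generate_buildup_curve(p, g, "DQF_MA", snr = 20, seed = 11)
  b <- generate_buildup_curve(p, g, "DQF_MA", snr = 20, seed = 11)
  c <- generate_buildup_curve(p, g, "DQF_MA", snr = 20, seed = 12)
  expect_identical(a$amplitude, b$amplitude)
  expect_false(identical(a$amplitude, c$amplitude))
  expect_length(a$amplitude, 45L)

  noiseless <- generate_buildup_curve(p, g, "TQF", snr = Inf, seed = 1)
  expect_identical(noiseless$amplitude, tqf_signal(p, g))

  # law of large numbers on the noise scale at 1e4 points
  big <- tau_grid(n = 1e4, tau_max = 18e-3)
  snr <- 20
  cv <- generate_buildup_curve(p, big, "DQF_MA", snr = snr, seed = 5)
  resid <- cv$amplitude - dqf_ma_signal(p, big)
  target <- max(abs(dqf_ma_signal(p, big))) / snr
  expect_lt(abs(sd(resid) / target - 1), 0.05)
})

test_that("flow-curve generator reproduces its model exactly without noise and round-trips a fit", {
  pl <- list(kind = "PL", pars = c(K = 1.56, n = 0.322))
  rg <- default_rate_grid()
  cl <- generate_flow_curve(pl, rg, noise_cv = 0, replicate_dispersion = 0,
                            n_replicates = 2, seed = 9)
  expect_equal(cl[[1]]$stress_Pa, model_stress(pl, rg), tolerance = 1e-15)
  expect_identical(cl[[1]]$stress_Pa, cl[[2]]$stress_Pa)

  fit <- fit_constitutive(cl[[1]], "PL")
  expect_equal(unname(fit$pars[["n"]]), 0.322, tolerance = 1e-3 / 0.322)

  # replicate yield-stress dispersion matches the configured spread
  hb <- kc_flow_row(283, "HB")
  cl2 <- generate_flow_curve(list(kind = "HB", pars = hb$pars),
                             rg, noise_cv = 0, replicate_dispersion = hb$sds,
                             n_replicates = 40, seed = 21)
  drawn <- vapply(cl2, function(cv) attr(cv, "pars")[["sigma_y"]], numeric(1))
  expect_lt(abs(sd(drawn) - 0.02), 0.01)
})

test_that("helix-coil model calibration places the crossover and viscosity drop where configured", {
  hc <- helix_coil_model()
  # sigmoid midpoint
  expect_equal(hc_helix_fraction(hc, hc$T_mid), 0.5, tolerance = 1e-12)
  # implied crossover of the noiseless moduli equals the configured target
  Tg <- seq(283, 313, by = 0.05)
  ts <- generate_temperature_sweep(hc, Tg, noise_rel = 0)
  cx <- detect_crossover(ts$sweep)
  expect_equal(cx$temperature_K, 301.7, tolerance = 0.1 / 301.7)
  expect_false(cx$multiple)
  # two-orders-of-magnitude viscosity drop over the ramp
  eta <- ts$viscosity$viscosity_Pa_s
  expect_gte(eta[1] / eta[length(eta)], 100)
  # coupling/rate laws calibrated by least squares match the closed form
  sh <- kc_mqf_shear_series()
  ora <- oracle_linreg(sh$shear_rate_per_s, sh$nu_eff_Hz)
  expect_equal(hc$nu0, ora$intercept, tolerance = 1e-9)
  expect_equal(hc$nu_slope, ora$slope, tolerance = 1e-9)
  expect_equal(hc$nu0, 100.23469387755104, tolerance = 1e-10)
  expect_equal(hc$nu_slope, 1.3634764250527802, tolerance = 1e-10)
})

test_that("MQF condition table encodes the presence/absence phenomenology", {
  hc <- helix_coil_model()
  tab <- generate_mqf_condition_table(hc, c(288, 295, 303, 313),
                                      c(0, 11.6, 29, 58, 87))
  rest <- tab[tab$shear_rate_per_s == 0, ]
  expect_true(all(rest$nu_eff_Hz == 0))
  expect_true(all(rest$R2slow_per_s == rest$R2fast_per_s))
  expect_true(all(!rest$signal))

  hot <- tab[tab$temperature_K >= hc$T_cutoff, ]
  expect_true(all(hot$nu_eff_Hz == 0))
  expect_true(all(!hot$signal))

  sheared <- tab[tab$shear_rate_per_s > 0 & tab$temperature_K < hc$T_cutoff, ]
  expect_true(all(sheared$nu_eff_Hz > 0))
  expect_true(all(sheared$R2slow_per_s < sheared$R2fast_per_s))
  # R2slow shear-independent: constant across rates at fixed temperature
  for (T in unique(sheared$temperature_K)) {
    expect_length(unique(sheared$R2slow_per_s[sheared$temperature_K == T]), 1L)
  }
  # coupling grows linearly with rate at fixed temperature
  at288 <- sheared[sheared$temperature_K == 288, ]
  slopes <- diff(at288$nu_eff_Hz) / diff(at288$shear_rate_per_s)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-9)
})

test_that("generate -> fit round trip recovers generating parameters within Monte-Carlo error", {
  p <- mqf_params(C0 = 1, C1 = 1, nu_eff = 111, R2fast = 135, R2slow = 46)
  st <- mqf_recovery_study(p, n_seeds = 50, snr = 20)
  for (q in c("nu_eff_Hz", "R2fast_per_s", "R2slow_per_s")) {
    expect_lt(abs(st$mean[[q]] - st$truth[[q]]), 2 * st$mc_se[[q]] + 1e-9)
  }
})
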