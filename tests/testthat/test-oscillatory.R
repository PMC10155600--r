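mk_sweep <- function(axis_kind, axis, gp, gpp, strain = NA, freq = NA, temp = NA) {
  structure(data.frame(axis_kind = axis_kind, axis_value = axis,
                       G_prime_Pa = gp, G_doubleprime_Pa = gpp,
                       strain_pct = strain, frequency_rad_s = freq,
                       temperature_K = temp),
            class = c("oscillatory_sweep", "data.frame"))
}

test_that("derived viscoelastic quantities follow their identities", {
  sw <- mk_sweep("frequency", c(1, 1, 1), c(2, 3, 0), c(2, 4, 5), freq = 1)
  dv <- derive_visco(sw, noise_floor = 0.1)
  expect_equal(dv$tan_delta[1], 1)
  expect_equal(dv$eta_star_Pa_s[2], 5)           # 3-4-5 identity
  expect_identical(dv$tan_delta[3], Inf)          # elastic response lost
  expect_error(derive_visco(mk_sweep("frequency", 1, 1, 1, freq = 0)), "> 0")
  # triangle inequality: eta* omega bounds each modulus
  set.seed(8)
  gp <- runif(20, 0, 5); gpp <- runif(20, 0, 5); om <- runif(20, 0.5, 50)
  dv2 <- derive_visco(mk_sweep("frequency", om, gp, gpp, freq = om))
  expect_true(all(dv2$eta_star_Pa_s * om >= gp - 1e-12))
  expect_true(all(dv2$eta_star_Pa_s * om >= gpp - 1e-12))
})

test_that("crossover detection matches the analytic intersection of log-linear moduli", {
  Tg <- seq(280, 320, by = 0.5)
  # ln G' = 10 - 0.1 T', ln G'' = const: closed-form crossing
  const <- 7.3
  T_exact <- (10 - const) / 0.1 + 280   # in the shifted variable T' = T - 280
  sw <- mk_sweep("temperature", Tg, exp(10 - 0.1 * (Tg - 280)), exp(const),
                 temp = Tg)
  cx <- detect_crossover(sw)
  expect_equal(cx$temperature_K, T_exact, tolerance = 1e-6)
  expect_false(cx$multiple)

  # no sign change: none
  none <- detect_crossover(mk_sweep("temperature", Tg, exp(Tg / 50) * 10,
                                    exp(Tg / 50), temp = Tg))
  expect_true(is.na(none$temperature_K))

  # multiple crossings: lowest returned and flagged
  gp <- c(2, 0.5, 2, 0.5); gpp <- c(1, 1, 1, 1); Ts <- c(290, 295, 300, 305)
  multi <- detect_crossover(mk_sweep("temperature", Ts, gp, gpp, temp = Ts))
  expect_true(multi$multiple)
  expect_lt(multi$temperature_K, 295)
})

test_that("LVR detection honours the plateau criterion and scaling invariance", {
  # constant storage modulus: LVR spans the whole range
  gam <- 10 ^ seq(-2, 3, length.out = 40)
  flat <- mk_sweep("strain", gam, rep(5, 40), rep(1, 40), strain = gam)
  expect_equal(lvr_extent(flat)$gamma_lvr_pct, 1000)

  # constructed piecewise curve dropping exactly 5% at 50% strain
  gam2 <- c(0.01, 0.1, 1, 5, 10, 50, 120, 300)
  gp2 <- c(1, 1, 1, 1, 1, 0.95, 0.7, 0.3)
  br <- lvr_extent(mk_sweep("strain", gam2, gp2, 0.2, strain = gam2))
  expect_equal(br$gamma_lvr_pct, 50, tolerance = 1e-9)
  # invariant under uniform scaling of G'
  br_scaled <- lvr_extent(mk_sweep("strain", gam2, 137 * gp2, 0.2, strain = gam2))
  expect_equal(br_scaled$gamma_lvr_pct, br$gamma_lvr_pct, tolerance = 1e-12)

  # calibrated synthetic amplitude sweep: 20% extent
  hc <- helix_coil_model()
  lv <- lvr_extent(generate_amplitude_sweep(hc))
  expect_equal(lv$gamma_lvr_pct, 20, tolerance = 0.02)
})

test_that("Cox-Merz comparison measures relative deviation at matched abscissae", {
  om <- 10 ^ seq(-1, 2, length.out = 20)
  eta <- data.frame(shear_rate_per_s = om, viscosity_Pa_s = 2 * om ^ -0.5)
  star_same <- data.frame(frequency_rad_s = om, eta_star_Pa_s = 2 * om ^ -0.5)
  same <- cox_merz_check(star_same, eta)
  expect_true(same$holds)
  expect_equal(same$max_rel_deviation, 0, tolerance = 1e-12)

  star_off <- data.frame(frequency_rad_s = om, eta_star_Pa_s = 1.3 * 2 * om ^ -0.5)
  off <- cox_merz_check(star_off, eta)
  expect_false(off$holds)
  expect_equal(off$max_rel_deviation, 0.3, tolerance = 1e-9)

  # disjoint ranges: undefined, flagged
  far <- data.frame(frequency_rad_s = om * 1e6, eta_star_Pa_s = om)
  expect_true(is.na(cox_merz_check(far, eta)$holds))
})

test_that("the synthetic fluid crosses from entangled to Cox-Merz behaviour with temperature", {
  hc <- helix_coil_model()
  dev_at <- function(T) {
    fs <- derive_visco(generate_frequency_sweep(hc, T, noise_rel = 0))
    sv <- generate_steady_viscosity(hc, T, noise_rel = 0)
    cox_merz_check(fs, sv)
  }
  expect_false(dev_at(288)$holds)
  expect_true(dev_at(303)$holds)
  expect_true(dev_at(308)$holds)
})
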