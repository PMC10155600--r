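#' Configuration of a synthetic study
#'
#' Bundles the knobs of the synthetic emulation of the sheared carrageenan
#' study: RNG seed, per-spectrum signal-to-noise ratio, number of creation-time
#' increments, replicate count for flow curves, and the condition lists.
#'
#' @param seed Integer RNG seed; every generator draws from it.
#' @param snr Target per-curve signal-to-noise ratio (> 0, may be `Inf`).
#' @param n_tau Number of tau increments per build-up curve (default 45).
#' @param n_replicates Flow-curve replicates per temperature (default 20; see
#'   the methods vignette for the power analysis behind this choice).
#' @param temperature_list Temperatures, K (must lie in 278-320 K).
#' @param shear_rate_list Shear rates, s^-1.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, snr = 20, n_tau = 45L,
                             n_replicates = 20L,
                             temperature_list = c(288, 291, 295, 298, 303, 313),
                             shear_rate_list = c(0, 11.6, 29, 58, 87)) {
  if (!is.finite(seed)) stop("seed must be a finite integer", call. = FALSE)
  if (!(snr > 0)) stop("snr must be > 0 (Inf allowed)", call. = FALSE)
  if (n_tau < 2L) stop("n_tau must be >= 2", call. = FALSE)
  if (any(temperature_list < 278 | temperature_list > 320)) {
    stop("temperatures must lie within 278-320 K", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), snr = snr, n_tau = as.integer(n_tau),
                 n_replicates = as.integer(n_replicates),
                 temperature_list = temperature_list,
                 shear_rate_list = shear_rate_list),
            class = "synthetic_config")
}

#' Helix-coil phenomenology of the carrageenan fluid
#'
#' A phenomenological model of the temperature behaviour of the 0.5%
#' kappa-carrageenan fluid, built around the helix fraction
#' \deqn{\varphi(T) = 1 / (1 + e^{(T - T_{mid})/\Delta T}),}
#' which drives the storage and loss moduli, the steady-shear viscosity, the
#' rate index, and the shear-induced residual quadrupolar coupling. The
#' low-temperature storage-modulus scale `G0_prime` is not free: it is solved
#' analytically so that the modulus crossover implied by the model falls
#' exactly at `T_crossover`.
#'
#' The coupling/relaxation laws are calibrated by ordinary least squares to
#' the reference parameter tables ([kc_mqf_shear_series()],
#' [kc_mqf_temperature_series()]): the coupling is linear in shear rate,
#' scaled by a melt factor that reaches zero at `T_cutoff`; the fast rate is
#' Arrhenius in temperature and weakly linear in shear rate; the slow rate is
#' shear-independent and weakly linear in temperature.
#'
#' @param T_mid Sigmoid midpoint, K.
#' @param delta_T Transition width, K (> 0).
#' @param T_crossover Target modulus-crossover temperature, K.
#' @param G0_doubleprime Structural loss-modulus scale, Pa.
#' @param exp_Gp,exp_Gpp Helix-fraction exponents of G' and G''.
#' @param eta_high High-temperature Newtonian viscosity, Pa s.
#' @param visc_amp,visc_exp Amplitude and helix-fraction exponent of the
#'   structural viscosity enhancement `eta(T) = eta_high (1 + visc_amp *
#'   phi(T)^visc_exp)`.
#' @param omega_ref Reference radial frequency for one-point oscillatory
#'   quantities, rad s^-1.
#' @param struct_amp,struct_exp Structural elastic enhancement of the complex
#'   viscosity over the steady viscosity, `eta* = eta (1 + struct_amp *
#'   phi^struct_exp)`; controls where the Cox-Merz rule holds.
#' @param T_cutoff Temperature at and above which multiple-quantum signals
#'   vanish, K.
#' @param T_ref Reference temperature of the shear-series calibration, K.
#' @param R2_iso Isotropic (no-shear) transverse relaxation rate, s^-1.
#' @param n_low Low-temperature (helix) power-law rate index.
#' @param lvr_strain_pct Linear-viscoelastic-region extent, % strain.
#' @param amp_exponent Sharpness of the amplitude-sweep modulus decay.
#' @return Object of class `helix_coil_model` with the calibrated
#'   coefficients attached.
#' @export
helix_coil_model <- function(T_mid = 299, delta_T = 3, T_crossover = 301.7,
                             G0_doubleprime = 2, exp_Gp = 4, exp_Gpp = 2,
                             eta_high = 0.014, visc_amp = 115, visc_exp = 2,
                             omega_ref = 12, struct_amp = 1.2, struct_exp = 2,
                             T_cutoff = 303, T_ref = 288, R2_iso = 35,
                             n_low = 0.35, lvr_strain_pct = 20,
                             amp_exponent = 2) {
  if (delta_T <= 0) stop("delta_T must be > 0", call. = FALSE)
  hc <- list(T_mid = T_mid, delta_T = delta_T, T_crossover = T_crossover,
             G0_doubleprime = G0_doubleprime, exp_Gp = exp_Gp, exp_Gpp = exp_Gpp,
             eta_high = eta_high, visc_amp = visc_amp, visc_exp = visc_exp,
             omega_ref = omega_ref, struct_amp = struct_amp,
             struct_exp = struct_exp, T_cutoff = T_cutoff, T_ref = T_ref,
             R2_iso = R2_iso, n_low = n_low,
             lvr_strain_pct = lvr_strain_pct, amp_exponent = amp_exponent)

  # coupling-vs-shear line and fast-rate-vs-shear line from the shear series
  sh <- kc_mqf_shear_series()
  cf_nu <- stats::coef(stats::lm(nu_eff_Hz ~ shear_rate_per_s, data = sh))
  cf_rf <- stats::coef(stats::lm(R2fast_per_s ~ shear_rate_per_s, data = sh))
  hc$nu0 <- cf_nu[[1]]; hc$nu_slope <- cf_nu[[2]]
  hc$r2f0 <- cf_rf[[1]]; hc$r2f_slope <- cf_rf[[2]]

  # Arrhenius factor of the fast rate and linear trend of the slow rate from
  # the temperature series
  te <- kc_mqf_temperature_series()
  te <- te[te$signal, ]
  cf_ar <- stats::coef(stats::lm(log(1 / te$R2fast_per_s) ~ I(1 / te$temperature_K)))
  hc$arrhenius_B <- -cf_ar[[2]]  # K; h(T) = exp(B (1/T - 1/T_ref))
  cf_rs <- stats::coef(stats::lm(te$R2slow_per_s ~ te$temperature_K))
  hc$r2s0 <- cf_rs[[1]]; hc$r2s_slope <- cf_rs[[2]]

  # storage-modulus scale solved so the implied crossover sits at T_crossover
  ph <- hc_helix_fraction(hc, T_crossover)
  hc$G0_prime <- (G0_doubleprime * ph ^ exp_Gpp +
                    hc_viscosity(hc, T_crossover) * omega_ref) / ph ^ exp_Gp
  structure(hc, class = "helix_coil_model")
}

#' Helix fraction of the sigmoid transition
#' @param hc A [helix_coil_model()].
#' @param temperature_K Temperatures, K.
#' @return Helix fraction in (0, 1); 1/2 at `T_mid`.
#' @export
hc_helix_fraction <- function(hc, temperature_K) {
  1 / (1 + exp((temperature_K - hc$T_mid) / hc$delta_T))
}

#' Steady-shear viscosity of the helix-coil model at the reference rate
#' @inheritParams hc_helix_fraction
#' @return Viscosity, Pa s (at the 10 s^-1 reference shear rate).
#' @export
hc_viscosity <- function(hc, temperature_K) {
  hc$eta_high * (1 + hc$visc_amp * hc_helix_fraction(hc, temperature_K) ^ hc$visc_exp)
}

# Noiseless moduli of the temperature sweep at omega_ref.
hc_G_prime <- function(hc, temperature_K) {
  hc$G0_prime * hc_helix_fraction(hc, temperature_K) ^ hc$exp_Gp
}
hc_G_doubleprime <- function(hc, temperature_K) {
  hc$G0_doubleprime * hc_helix_fraction(hc, temperature_K) ^ hc$exp_Gpp +
    hc_viscosity(hc, temperature_K) * hc$omega_ref
}

# Temperature-dependent power-law rate index: helix-weighted between the
# low-temperature shear-thinning index and Newtonian behaviour.
hc_rate_index <- function(hc, temperature_K) {
  1 - (1 - hc$n_low) * hc_helix_fraction(hc, temperature_K)
}

# Steady shear-thinning viscosity at arbitrary rate (power-law around the
# 10 s^-1 reference point).
hc_steady_viscosity <- function(hc, temperature_K, rate) {
  hc_viscosity(hc, temperature_K) * (rate / 10) ^ (hc_rate_index(hc, temperature_K) - 1)
}

#' Generate one synthetic MQF build-up curve
#'
#' Evaluates the DQF-MA or TQF forward model on the tau grid and adds i.i.d.
#' Gaussian noise with standard deviation `max(|model|) / snr`. When the
#' forward model is identically zero (an absence-of-signal condition), the
#' amplitude parameter of the requested filter is used as the noise reference
#' instead, so null conditions still carry instrument noise.
#'
#' @param params An [mqf_params()] generating truth.
#' @param grid A [tau_grid()].
#' @param filter_kind `"DQF_MA"` or `"TQF"`.
#' @param snr Signal-to-noise ratio (> 0; `Inf` gives the noiseless model).
#' @param seed Integer seed; identical seeds give identical curves.
#' @param sigma Optional explicit noise standard deviation (a.u.), overriding
#'   the SNR rule (used e.g. for pure-noise null studies).
#' @param temperature_K,shear_rate_per_s Condition metadata carried on the
#'   curve.
#' @return A `buildup_curve`: list with `tau`, `amplitude`, `filter_kind`,
#'   `temperature_K`, `shear_rate_per_s`, `snr`, `noise_sigma`, `seed`,
#'   `truth`.
#' @export
generate_buildup_curve <- function(params, grid = tau_grid(),
                                   filter_kind = c("DQF_MA", "TQF"),
                                   snr = 20, seed = 1L, sigma = NULL,
                                   temperature_K = NA_real_,
                                   shear_rate_per_s = NA_real_) {
  filter_kind <- match.arg(filter_kind)
  params <- as_mqf_params(params)
  if (!(snr > 0)) stop("snr must be > 0", call. = FALSE)
  model <- mqf_forward(params, grid, filter_kind)
  if (is.null(sigma)) {
    ref <- max(abs(model))
    if (ref == 0) {
      ref <- abs(switch(filter_kind, DQF_MA = params$C0, TQF = params$C1))
    }
    sigma <- if (is.finite(snr)) ref / snr else 0
  }
  amplitude <- if (sigma > 0) {
    withr::with_seed(as.integer(seed), model + stats::rnorm(length(model), 0, sigma))
  } else model
  structure(list(tau = as.numeric(grid), amplitude = amplitude,
                 filter_kind = filter_kind,
                 temperature_K = temperature_K,
                 shear_rate_per_s = shear_rate_per_s,
                 snr = snr, noise_sigma = sigma, seed = as.integer(seed),
                 truth = params),
            class = "buildup_curve")
}

#' @export
print.buildup_curve <- function(x, ...) {
  cat(sprintf("%s build-up curve: %d tau points (%.3g-%.3g ms), sigma = %.3g a.u.\n",
              x$filter_kind, length(x$tau), 1e3 * min(x$tau), 1e3 * max(x$tau),
              x$noise_sigma))
  invisible(x)
}

#' Generate replicate synthetic flow curves
#'
#' Each replicate draws its constitutive parameters from Gaussian dispersion
#' around the supplied model (truncated at the physical bounds sigma_y >= 0,
#' K > 0, n > 0, eta > 0), then evaluates the stress on the rate grid and
#' applies multiplicative Gaussian noise with coefficient of variation
#' `noise_cv`.
#'
#' @param model List with `kind` (`"HB"`, `"PL"`, `"N"`) and `pars` (named as
#'   in [constitutive_fit()]), e.g. a [constitutive_fit()] or a
#'   reference-row parameter set.
#' @param rate_grid Shear rates, s^-1 (> 0, increasing).
#' @param noise_cv Multiplicative stress-noise CV (>= 0; default 0.02).
#' @param replicate_dispersion Named numeric vector of per-parameter standard
#'   deviations (0 for a deterministic replicate set).
#' @param n_replicates Number of replicates.
#' @param temperature_K Condition metadata.
#' @param seed Integer seed.
#' @return List of data frames (one per replicate) with columns
#'   `temperature_K`, `replicate`, `shear_rate_per_s`, `stress_Pa`; the drawn
#'   parameters are attached as attribute `"pars"`.
#' @export
generate_flow_curve <- function(model, rate_grid = default_rate_grid(),
                                noise_cv = 0.02, replicate_dispersion = 0,
                                n_replicates = 1L, temperature_K = NA_real_,
                                seed = 1L) {
  kind <- match.arg(model$kind, c("HB", "PL", "N"))
  if (any(rate_grid <= 0)) stop("rates must be > 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  base <- model$pars
  disp <- rep(0, length(base)); names(disp) <- names(base)
  if (!identical(replicate_dispersion, 0)) {
    disp[names(replicate_dispersion)] <- replicate_dispersion
  }
  lowers <- c(sigma_y = 0, K = 1e-12, n = 1e-6, eta = 1e-12)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_replicates), function(r) {
      pars <- base + stats::rnorm(length(base), 0, disp)
      pars <- pmax(pars, lowers[names(base)])
      stress <- model_stress(list(kind = kind, pars = pars), rate_grid)
      if (noise_cv > 0) {
        stress <- stress * (1 + stats::rnorm(length(stress), 0, noise_cv))
        stress <- pmax(stress, 1e-12)
      }
      out <- data.frame(temperature_K = temperature_K, replicate = r,
                        shear_rate_per_s = rate_grid, stress_Pa = stress)
      attr(out, "pars") <- pars
      out
    })
  })
}

new_sweep <- function(axis_kind, axis_value, G_prime, G_doubleprime,
                      strain_pct = NA_real_, frequency_rad_s = NA_real_,
                      temperature_K = NA_real_) {
  out <- data.frame(axis_kind = axis_kind, axis_value = axis_value,
                    G_prime_Pa = G_prime, G_doubleprime_Pa = G_doubleprime,
                    strain_pct = strain_pct, frequency_rad_s = frequency_rad_s,
                    temperature_K = temperature_K)
  class(out) <- c("oscillatory_sweep", "data.frame")
  out
}

#' Generate a synthetic oscillatory temperature sweep
#'
#' Moduli at fixed strain and frequency over a temperature ramp, plus the
#' companion steady-shear viscosity series at 10 s^-1, as produced by the
#' helix-coil model. The noiseless moduli cross exactly at the model's
#' configured crossover temperature; the viscosity series spans about two
#' orders of magnitude over 283-313 K.
#'
#' @param hc A [helix_coil_model()].
#' @param T_grid Increasing temperatures, K.
#' @param strain Strain amplitude, % (metadata; the model is linear).
#' @param frequency Radial frequency, rad s^-1 (defaults to the model's
#'   `omega_ref`).
#' @param noise_rel Relative Gaussian noise on moduli and viscosity
#'   (default 0.01).
#' @param seed Integer seed.
#' @return List with `sweep` (an oscillatory sweep over temperature) and
#'   `viscosity` (data frame `temperature_K`, `shear_rate_per_s`,
#'   `viscosity_Pa_s`).
#' @export
generate_temperature_sweep <- function(hc, T_grid = seq(283, 313, by = 0.5),
                                       strain = 1, frequency = hc$omega_ref,
                                       noise_rel = 0.01, seed = 1L) {
  if (length(T_grid) < 2L) stop("empty temperature grid", call. = FALSE)
  if (any(diff(T_grid) <= 0)) stop("T_grid must be increasing", call. = FALSE)
  gp <- hc_G_prime(hc, T_grid)
  gpp <- hc_G_doubleprime(hc, T_grid)
  eta <- hc_viscosity(hc, T_grid)
  if (noise_rel > 0) {
    withr::with_seed(as.integer(seed), {
      gp <- gp * (1 + stats::rnorm(length(gp), 0, noise_rel))
      gpp <- gpp * (1 + stats::rnorm(length(gpp), 0, noise_rel))
      eta <- eta * (1 + stats::rnorm(length(eta), 0, noise_rel))
    })
  }
  sweep <- new_sweep("temperature", T_grid, pmax(gp, 0), pmax(gpp, 0),
                     strain_pct = strain, frequency_rad_s = frequency,
                     temperature_K = T_grid)
  list(sweep = sweep,
       viscosity = data.frame(temperature_K = T_grid, shear_rate_per_s = 10,
                              viscosity_Pa_s = pmax(eta, 1e-12)))
}

#' Generate a synthetic amplitude sweep
#'
#' Storage modulus with a low-strain plateau decaying as
#' `G'(gamma) = G_p / (1 + (gamma/gamma_b)^q)`, with `gamma_b` placed so the
#' 5% departure from the plateau falls exactly at the model's configured
#' linear-viscoelastic-region extent.
#'
#' @param hc A [helix_coil_model()].
#' @param temperature_K Temperature of the sweep, K.
#' @param strain_grid Strain amplitudes, % (increasing).
#' @param noise_rel Relative modulus noise (default 0: amplitude sweeps are
#'   used for exact detector calibration).
#' @param seed Integer seed.
#' @return An oscillatory sweep over strain.
#' @export
generate_amplitude_sweep <- function(hc, temperature_K = 288,
                                     strain_grid = 10 ^ seq(-2, 3, length.out = 51),
                                     noise_rel = 0, seed = 1L) {
  q <- hc$amp_exponent
  frac <- 0.05
  gamma_b <- hc$lvr_strain_pct * (frac / (1 - frac)) ^ (-1 / q)
  gp0 <- hc_G_prime(hc, temperature_K)
  gpp0 <- hc_G_doubleprime(hc, temperature_K)
  gp <- gp0 / (1 + (strain_grid / gamma_b) ^ q)
  gpp <- gpp0 / (1 + (strain_grid / (4 * gamma_b)) ^ q)
  if (noise_rel > 0) {
    withr::with_seed(as.integer(seed), {
      gp <- gp * (1 + stats::rnorm(length(gp), 0, noise_rel))
      gpp <- gpp * (1 + stats::rnorm(length(gpp), 0, noise_rel))
    })
  }
  new_sweep("strain", strain_grid, gp, gpp, strain_pct = strain_grid,
            frequency_rad_s = hc$omega_ref, temperature_K = temperature_K)
}

#' Generate a synthetic frequency sweep at one temperature
#'
#' Loss modulus follows the steady-shear viscosity identified at
#' `rate = omega` (the Cox-Merz baseline); the storage modulus adds the
#' structural elastic contribution that raises the complex viscosity above
#' the steady viscosity by the factor `1 + struct_amp * phi(T)^struct_exp`.
#' Below the transition this makes the Cox-Merz comparison fail; above it,
#' the two viscosities agree.
#'
#' @param hc A [helix_coil_model()].
#' @param temperature_K Temperature, K.
#' @param omega_grid Radial frequencies, rad s^-1.
#' @param noise_rel Relative modulus noise (default 0.01).
#' @param seed Integer seed.
#' @return An oscillatory sweep over frequency.
#' @export
generate_frequency_sweep <- function(hc, temperature_K = 288,
                                     omega_grid = 10 ^ seq(-1, 2, length.out = 25),
                                     noise_rel = 0.01, seed = 1L) {
  phi <- hc_helix_fraction(hc, temperature_K)
  boost <- 1 + hc$struct_amp * phi ^ hc$struct_exp
  eta_s <- hc_steady_viscosity(hc, temperature_K, omega_grid)
  gpp <- eta_s * omega_grid
  gp <- gpp * sqrt(boost ^ 2 - 1)
  if (noise_rel > 0) {
    withr::with_seed(as.integer(seed), {
      gp <- gp * (1 + stats::rnorm(length(gp), 0, noise_rel))
      gpp <- gpp * (1 + stats::rnorm(length(gpp), 0, noise_rel))
    })
  }
  new_sweep("frequency", omega_grid, pmax(gp, 0), pmax(gpp, 0),
            strain_pct = 1, frequency_rad_s = omega_grid,
            temperature_K = temperature_K)
}

#' Generate a steady-shear viscosity curve at one temperature
#'
#' The steady companion of [generate_frequency_sweep()] for Cox-Merz
#' comparisons.
#'
#' @inheritParams generate_frequency_sweep
#' @param rate_grid Shear rates, s^-1.
#' @return Data frame with `shear_rate_per_s`, `viscosity_Pa_s`,
#'   `temperature_K`.
#' @export
generate_steady_viscosity <- function(hc, temperature_K = 288,
                                      rate_grid = 10 ^ seq(-1, 2, length.out = 25),
                                      noise_rel = 0.01, seed = 2L) {
  eta <- hc_steady_viscosity(hc, temperature_K, rate_grid)
  if (noise_rel > 0) {
    eta <- withr::with_seed(as.integer(seed),
                            eta * (1 + stats::rnorm(length(eta), 0, noise_rel)))
  }
  data.frame(shear_rate_per_s = rate_grid, viscosity_Pa_s = pmax(eta, 1e-12),
             temperature_K = temperature_K)
}

#' MQF parameters implied by the helix-coil model for each condition
#'
#' Builds the generating-truth table of [mqf_params()] across a
#' (temperature, shear rate) grid:
#' \itemize{
#'   \item no shear, any temperature: no alignment and fast tumbling, so
#'     `nu_eff = 0` and `R2slow = R2fast` (mono-exponential, the isotropic
#'     rate `R2_iso`) - no multiple-quantum signal of either kind;
#'   \item at or above `T_cutoff`: `nu_eff = 0` and mono-exponential
#'     relaxation - no signal;
#'   \item otherwise `nu_eff = melt(T) * (nu0 + nu_slope * rate)` with a melt
#'     factor decreasing linearly from 1 at `T_ref` to 0 at `T_cutoff`;
#'     `R2fast` Arrhenius in temperature, weakly linear in rate; `R2slow`
#'     shear-independent.
#' }
#'
#' @param hc A [helix_coil_model()].
#' @param temperatures Temperatures, K.
#' @param shear_rates Shear rates, s^-1 (0 allowed).
#' @return Data frame with columns `temperature_K`, `shear_rate_per_s`, `C0`,
#'   `C1`, `nu_eff_Hz`, `R2fast_per_s`, `R2slow_per_s`, `signal`.
#' @export
generate_mqf_condition_table <- function(hc, temperatures = c(288, 295, 303, 313),
                                         shear_rates = c(0, 11.6, 29, 58, 87)) {
  grid <- expand.grid(shear_rate_per_s = shear_rates, temperature_K = temperatures,
                      KEEP.OUT.ATTRS = FALSE)
  melt <- pmin(pmax((hc$T_cutoff - grid$temperature_K) /
                      (hc$T_cutoff - hc$T_ref), 0), 1)
  sheared <- grid$shear_rate_per_s > 0 & grid$temperature_K < hc$T_cutoff
  nu <- ifelse(sheared, pmax(0, melt * (hc$nu0 + hc$nu_slope * grid$shear_rate_per_s)), 0)
  hT <- exp(hc$arrhenius_B * (1 / grid$temperature_K - 1 / hc$T_ref))
  r2f <- ifelse(sheared, pmax((hc$r2f0 + hc$r2f_slope * grid$shear_rate_per_s) * hT,
                              hc$R2_iso), hc$R2_iso)
  r2s <- ifelse(sheared, pmax(hc$r2s0 + hc$r2s_slope * grid$temperature_K, 1), r2f)
  data.frame(temperature_K = grid$temperature_K,
             shear_rate_per_s = grid$shear_rate_per_s,
             C0 = 1, C1 = 1, nu_eff_Hz = nu, R2fast_per_s = r2f,
             R2slow_per_s = r2s, signal = nu > 0)
}
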