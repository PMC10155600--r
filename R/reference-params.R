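#' Reference MQF parameters of the sheared carrageenan fluid: shear series
#'
#' Fitted DQF-MA/TQF parameters reported for a 0.5% aqueous kappa-carrageenan
#' fluid sheared in a Couette cell at 288 K, at four shear rates. These are
#' the generating truths for the package's parameter-recovery studies at
#' fixed temperature.
#'
#' @return A data frame with columns `shear_rate_per_s`, `nu_eff_Hz`,
#'   `nu_eff_se_Hz`, `R2fast_per_s`, `R2fast_se_per_s`, `R2slow_per_s`,
#'   `R2slow_se_per_s`.
#' @seealso [kc_mqf_temperature_series()], [kc_flow_models()]
#' @export
kc_mqf_shear_series <- function() {
  data.frame(
    shear_rate_per_s = c(11.6, 29, 58, 87),
    nu_eff_Hz        = c(111, 142, 188, 213),
    nu_eff_se_Hz     = c(7, 7, 6, 7),
    R2fast_per_s     = c(135, 145, 153, 170),
    R2fast_se_per_s  = c(8, 8, 9, 10),
    R2slow_per_s     = c(46, 52, 46, 53),
    R2slow_se_per_s  = c(3, 3, 3, 5)
  )
}

#' Reference MQF parameters: temperature series at 58 s^-1
#'
#' Fitted DQF-MA/TQF parameters at a fixed shear rate of 58 s^-1 across the
#' helix-coil transition. Above 303 K no multiple-quantum signal exists and
#' the parameter columns are `NA` (`signal = FALSE`).
#'
#' @return A data frame with columns `temperature_K`, `signal`, `nu_eff_Hz`,
#'   `nu_eff_se_Hz`, `R2fast_per_s`, `R2fast_se_per_s`, `R2slow_per_s`,
#'   `R2slow_se_per_s`.
#' @export
kc_mqf_temperature_series <- function() {
  data.frame(
    temperature_K    = c(288, 291, 295, 298, 303, 313),
    signal           = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    nu_eff_Hz        = c(188, 163, 107, 52, NA, NA),
    nu_eff_se_Hz     = c(6, 4, 2, 1, NA, NA),
    R2fast_per_s     = c(153, 136, 79, 42, NA, NA),
    R2fast_se_per_s  = c(9, 5, 4, 1, NA, NA),
    R2slow_per_s     = c(46, 48, 39, 34, NA, NA),
    R2slow_se_per_s  = c(3, 3, 3, 2, NA, NA)
  )
}

#' Reference constitutive-model parameters of the carrageenan fluid
#'
#' Replicate-averaged Herschel-Bulkley (HB), power-law (PL) and Newtonian (N)
#' parameters of the 0.5% kappa-carrageenan fluid at five temperatures, with
#' their replicate standard deviations. The `chosen` column marks the model
#' the replicate-dispersion cascade accepts at each temperature.
#'
#' @return A data frame with one row per (temperature, model): columns
#'   `temperature_K`, `kind`, `sigma_y_Pa`, `sigma_y_sd_Pa`, `K_Pa_sn`,
#'   `K_sd_Pa_sn`, `n`, `n_sd`, `eta_Pa_s`, `eta_sd_Pa_s`, `chosen`.
#' @export
kc_flow_models <- function() {
  data.frame(
    temperature_K = c(283, 283, 288, 288, 295, 295, 303, 313, 313),
    kind          = c("HB", "PL", "HB", "PL", "HB", "PL", "PL", "PL", "N"),
    sigma_y_Pa    = c(0.06, NA, 0.02, NA, 0.1, NA, NA, NA, NA),
    sigma_y_sd_Pa = c(0.02, NA, 0.07, NA, 0.2, NA, NA, NA, NA),
    K_Pa_sn       = c(1.49, 1.56, 1.23, 1.24, 0.49, 0.58, 0.045, 0.018, NA),
    K_sd_Pa_sn    = c(0.05, 0.07, 0.08, 0.08, 0.04, 0.06, 0.002, 0.001, NA),
    n             = c(0.35, 0.322, 0.36, 0.35, 0.47, 0.44, 0.824, 0.946, NA),
    n_sd          = c(0.03, 0.001, 0.01, 0.01, 0.01, 0.02, 0.006, 0.002, NA),
    eta_Pa_s      = c(NA, NA, NA, NA, NA, NA, NA, NA, 0.0140),
    eta_sd_Pa_s   = c(NA, NA, NA, NA, NA, NA, NA, NA, 0.0001),
    chosen        = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  )
}

# Reference row -> mqf_params (C0/C1 amplitudes are arbitrary units; 1 by
# convention for synthetic studies).
kc_params_at_shear <- function(shear_rate) {
  tab <- kc_mqf_shear_series()
  i <- match(shear_rate, tab$shear_rate_per_s)
  if (is.na(i)) stop("no reference shear-series row at ", shear_rate, " s^-1", call. = FALSE)
  mqf_params(C0 = 1, C1 = 1, nu_eff = tab$nu_eff_Hz[i],
             R2fast = tab$R2fast_per_s[i], R2slow = tab$R2slow_per_s[i])
}

kc_params_at_temperature <- function(temperature) {
  tab <- kc_mqf_temperature_series()
  i <- match(temperature, tab$temperature_K)
  if (is.na(i)) stop("no reference temperature-series row at ", temperature, " K", call. = FALSE)
  if (!tab$signal[i]) return(NULL)
  mqf_params(C0 = 1, C1 = 1, nu_eff = tab$nu_eff_Hz[i],
             R2fast = tab$R2fast_per_s[i], R2slow = tab$R2slow_per_s[i])
}

# Reference constitutive row -> constitutive_fit-like parameter list.
kc_flow_row <- function(temperature, kind) {
  tab <- kc_flow_models()
  i <- which(tab$temperature_K == temperature & tab$kind == kind)
  if (length(i) != 1L) {
    stop("no reference flow row at ", temperature, " K / ", kind, call. = FALSE)
  }
  row <- tab[i, ]
  switch(kind,
    HB = list(kind = "HB",
              pars = c(sigma_y = row$sigma_y_Pa, K = row$K_Pa_sn, n = row$n),
              sds  = c(sigma_y = row$sigma_y_sd_Pa, K = row$K_sd_Pa_sn, n = row$n_sd)),
    PL = list(kind = "PL",
              pars = c(K = row$K_Pa_sn, n = row$n),
              sds  = c(K = row$K_sd_Pa_sn, n = row$n_sd)),
    N  = list(kind = "N",
              pars = c(eta = row$eta_Pa_s),
              sds  = c(eta = row$eta_sd_Pa_s)))
}
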