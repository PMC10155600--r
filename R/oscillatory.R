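#' Derived viscoelastic quantities of an oscillatory sweep
#'
#' Computes the loss tangent `tan(delta) = G''/G'` and the complex viscosity
#' `eta* = sqrt(G'^2 + G''^2) / omega` per point. Where the storage modulus
#' falls at or below the noise floor, the loss tangent is flagged infinite
#' (the fluid has lost its elastic response).
#'
#' @param sweep An oscillatory sweep data frame (see
#'   [generate_frequency_sweep()]) with `G_prime_Pa`, `G_doubleprime_Pa` and
#'   a positive frequency in `frequency_rad_s`.
#' @param noise_floor Modulus noise floor, Pa (default 0).
#' @return The sweep with added columns `tan_delta` and `eta_star_Pa_s`.
#' @export
derive_visco <- function(sweep, noise_floor = 0) {
  omega <- sweep$frequency_rad_s
  if (any(!is.finite(omega)) || any(omega <= 0)) {
    stop("derive_visco: frequency must be > 0 for every point", call. = FALSE)
  }
  gp <- sweep$G_prime_Pa; gpp <- sweep$G_doubleprime_Pa
  sweep$tan_delta <- ifelse(gp > noise_floor, gpp / gp, Inf)
  sweep$eta_star_Pa_s <- sqrt(gp ^ 2 + gpp ^ 2) / omega
  sweep
}

#' Storage/loss modulus crossover temperature
#'
#' Finds the temperature at which G' = G'' on a temperature sweep by
#' log-linear interpolation between the grid points bracketing the sign
#' change of `log G' - log G''` (moduli vary exponentially with temperature
#' across the helix-coil transition, so interpolation is done in
#' log-modulus space). With several crossings the lowest is returned and
#' flagged.
#'
#' @param sweep An oscillatory sweep over temperature with both moduli
#'   present (> 0) on a common grid.
#' @return List with `temperature_K` (`NA` when G' - G'' never changes
#'   sign), `multiple` flag, and `n_crossings`.
#' @export
detect_crossover <- function(sweep) {
  T <- sweep$temperature_K
  gp <- sweep$G_prime_Pa; gpp <- sweep$G_doubleprime_Pa
  ok <- is.finite(gp) & is.finite(gpp) & gp > 0 & gpp > 0
  T <- T[ok]; d <- log(gp[ok]) - log(gpp[ok])
  if (length(T) < 2L) stop("detect_crossover: need >= 2 usable points", call. = FALSE)
  idx <- which(d[-length(d)] * d[-1] < 0)
  exact <- which(d == 0)
  crossings <- sort(c(T[exact],
                      vapply(idx, function(i) {
                        T[i] + (T[i + 1] - T[i]) * d[i] / (d[i] - d[i + 1])
                      }, numeric(1))))
  if (!length(crossings)) {
    return(list(temperature_K = NA_real_, multiple = FALSE, n_crossings = 0L))
  }
  list(temperature_K = crossings[[1]], multiple = length(crossings) > 1L,
       n_crossings = length(crossings))
}

#' Extent of the linear viscoelastic region
#'
#' The LVR extent is the largest strain up to which the storage modulus stays
#' within `fraction` (default 5%) of its low-strain plateau, the plateau
#' being the median of the first `n_plateau` points (robust to
#' non-monotone noise). The 5%-departure strain is located by linear
#' interpolation in log-strain between the bracketing grid points, so the
#' result does not snap to the grid. Invariant under uniform scaling of G'.
#'
#' @param sweep An oscillatory sweep over strain (`strain_pct` increasing).
#' @param fraction Allowed relative departure from the plateau.
#' @param n_plateau Number of low-strain points defining the plateau.
#' @return List with `gamma_lvr_pct`, `plateau_Pa`.
#' @export
lvr_extent <- function(sweep, fraction = 0.05, n_plateau = 5L) {
  gamma <- sweep$strain_pct; gp <- sweep$G_prime_Pa
  if (is.null(gamma) || any(!is.finite(gamma))) {
    stop("lvr_extent: needs a strain axis", call. = FALSE)
  }
  plateau <- stats::median(gp[seq_len(min(n_plateau, length(gp)))])
  rel <- abs(gp / plateau - 1)
  below <- rel <= fraction
  first_out <- which(!below)[1]
  if (is.na(first_out)) {
    return(list(gamma_lvr_pct = gamma[length(gamma)], plateau_Pa = plateau))
  }
  if (first_out == 1L) {
    return(list(gamma_lvr_pct = gamma[1], plateau_Pa = plateau))
  }
  i <- first_out - 1L
  lg <- log(gamma[i]) + (log(gamma[i + 1]) - log(gamma[i])) *
    (fraction - rel[i]) / (rel[i + 1] - rel[i])
  list(gamma_lvr_pct = exp(lg), plateau_Pa = plateau)
}

#' Cox-Merz comparison of complex and steady-shear viscosity
#'
#' The empirical Cox-Merz rule identifies the complex viscosity at radial
#' frequency omega with the steady viscosity at shear rate gamma-dot = omega
#' (numerically, rad s^-1 with s^-1). The sparser curve is interpolated onto
#' the other's grid in log-log space over the overlapping range, and the rule
#' is declared to hold when the maximum relative deviation does not exceed
#' `tolerance`.
#'
#' @param eta_star Data frame with `frequency_rad_s` and `eta_star_Pa_s`
#'   (e.g. [derive_visco()] of a frequency sweep).
#' @param eta Data frame with `shear_rate_per_s` and `viscosity_Pa_s`.
#' @param tolerance Relative deviation tolerance (default 0.10).
#' @return List with `holds`, `max_rel_deviation`, `overlap` (range used),
#'   `tolerance`; `holds = NA` and a zero-length overlap when the ranges do
#'   not intersect.
#' @export
cox_merz_check <- function(eta_star, eta, tolerance = 0.10) {
  x1 <- eta_star$frequency_rad_s; y1 <- eta_star$eta_star_Pa_s
  x2 <- eta$shear_rate_per_s; y2 <- eta$viscosity_Pa_s
  lo <- max(min(x1), min(x2)); hi <- min(max(x1), max(x2))
  if (!(hi > lo)) {
    return(list(holds = NA, max_rel_deviation = NA_real_,
                overlap = c(NA_real_, NA_real_), tolerance = tolerance))
  }
  keep <- x2 >= lo & x2 <= hi
  interp <- stats::approx(log(x1), log(y1), xout = log(x2[keep]))$y
  dev <- max(abs(exp(interp) / y2[keep] - 1))
  list(holds = dev <= tolerance, max_rel_deviation = dev,
       overlap = c(lo, hi), tolerance = tolerance)
}
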