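#' Constitutive model parameter container
#'
#' @param kind One of `"HB"` (Herschel-Bulkley), `"PL"` (power law),
#'   `"N"` (Newtonian).
#' @param sigma_y Yield stress, Pa (HB only, >= 0).
#' @param K Consistency, Pa s^n (HB, PL; > 0).
#' @param n Rate index, dimensionless (HB, PL; > 0; n < 1 is shear-thinning).
#' @param eta Newtonian viscosity, Pa s (N only; > 0).
#' @param se Optional named numeric vector of standard errors.
#' @param converged Logical convergence flag.
#' @return Object of class `constitutive_fit`.
#' @export
constitutive_fit <- function(kind, sigma_y = NULL, K = NULL, n = NULL,
                             eta = NULL, se = NULL, converged = TRUE) {
  kind <- match.arg(kind, c("HB", "PL", "N"))
  pars <- switch(kind,
    HB = c(sigma_y = as.numeric(sigma_y), K = as.numeric(K), n = as.numeric(n)),
    PL = c(K = as.numeric(K), n = as.numeric(n)),
    N  = c(eta = as.numeric(eta)))
  if (anyNA(pars) || length(pars) != switch(kind, HB = 3L, PL = 2L, N = 1L)) {
    stop("constitutive_fit: missing parameters for model ", kind, call. = FALSE)
  }
  if (kind == "HB" && pars[["sigma_y"]] < 0) stop("sigma_y must be >= 0", call. = FALSE)
  if (kind %in% c("HB", "PL") && (pars[["K"]] <= 0 || pars[["n"]] <= 0)) {
    stop("K and n must be > 0", call. = FALSE)
  }
  if (kind == "N" && pars[["eta"]] <= 0) stop("eta must be > 0", call. = FALSE)
  structure(list(kind = kind, pars = pars, se = se, converged = converged),
            class = "constitutive_fit")
}

#' @export
print.constitutive_fit <- function(x, ...) {
  cat(sprintf("Constitutive fit [%s]: %s\n", x$kind,
              paste(sprintf("%s = %.4g", names(x$pars), x$pars), collapse = ", ")))
  if (!is.null(x$se)) {
    cat("  SE: ", paste(sprintf("%s = %.3g", names(x$se), x$se), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Shear stress predicted by a constitutive model
#'
#' Evaluates sigma(gamma-dot) for the Herschel-Bulkley
#' (`sigma_y + K * rate^n`), power-law (`K * rate^n`) or Newtonian
#' (`eta * rate`) model.
#'
#' @param fit A [constitutive_fit()] (or a list with `kind` and `pars`).
#' @param shear_rate Non-negative shear rates, s^-1.
#' @return Stress, Pa (same length as `shear_rate`).
#' @export
model_stress <- function(fit, shear_rate) {
  if (any(shear_rate < 0)) stop("shear_rate must be >= 0", call. = FALSE)
  p <- fit$pars
  switch(fit$kind,
    HB = p[["sigma_y"]] + p[["K"]] * shear_rate ^ p[["n"]],
    PL = p[["K"]] * shear_rate ^ p[["n"]],
    N  = p[["eta"]] * shear_rate,
    stop("unknown constitutive model kind: ", fit$kind, call. = FALSE))
}

# Weighted residuals and analytic Jacobian for constant-CV least squares.
# The weights (1/stress-scale) are frozen within each Levenberg-Marquardt
# pass and refreshed between passes from the current model (IRLS): weights
# that track the noise draw (observation-based) or that are differentiated
# through (model-based residual ratios) both bias scale parameters by
# O(cv^2), whereas the frozen-weight estimating equation is unbiased to that
# order.
constitutive_residual <- function(theta, kind, rate, stress, w) {
  w * (model_stress(list(kind = kind, pars = theta), rate) - stress)
}

constitutive_jacobian <- function(theta, kind, rate, stress, w) {
  J <- switch(kind,
    HB = cbind(sigma_y = rep(1, length(rate)),
               K = rate ^ theta[["n"]],
               n = theta[["K"]] * rate ^ theta[["n"]] * log(rate)),
    PL = cbind(K = rate ^ theta[["n"]],
               n = theta[["K"]] * rate ^ theta[["n"]] * log(rate)),
    N  = cbind(eta = rate))
  J * w
}

#' Fit a constitutive model to a flow curve
#'
#' Iteratively reweighted nonlinear least squares (Levenberg-Marquardt with
#' inverse-stress weights refreshed from the current model between passes),
#' appropriate for flow curves spanning several decades with
#' constant-coefficient-of-variation noise. The Herschel-Bulkley yield stress
#' is bounded below at zero. Power-law fits are initialised from the exact
#' log-log linear regression; standard errors come from the weighted Jacobian
#' at the optimum.
#'
#' @param curve A data frame with columns `shear_rate_per_s` (> 0, strictly
#'   increasing within a replicate) and `stress_Pa`, e.g. one replicate of a
#'   [generate_flow_curve()] set.
#' @param kind `"HB"`, `"PL"` or `"N"`.
#' @return A [constitutive_fit()] with `se`, `converged`, `residual_norm`,
#'   and for HB a `coverage_ok` flag (TRUE when the rate range spans at least
#'   three decades, which yield-stress identification needs).
#' @export
fit_constitutive <- function(curve, kind = c("HB", "PL", "N")) {
  kind <- match.arg(kind)
  rate <- curve$shear_rate_per_s
  stress <- curve$stress_Pa
  if (length(rate) < 5L) stop("fit_constitutive: need >= 5 points", call. = FALSE)
  if (any(rate <= 0)) stop("fit_constitutive: shear rates must be > 0", call. = FALSE)
  if (any(stress <= 0)) stop("fit_constitutive: stresses must be > 0", call. = FALSE)

  # log-log regression: exact for noiseless power-law data
  ll <- stats::lm(log(stress) ~ log(rate))
  K0 <- exp(stats::coef(ll)[[1]]); n0 <- max(stats::coef(ll)[[2]], 1e-3)

  theta0 <- switch(kind,
    PL = c(K = K0, n = n0),
    N  = c(eta = stats::median(stress / rate)),
    HB = c(sigma_y = 0.5 * min(stress), K = K0, n = n0))
  lower <- switch(kind,
    PL = c(K = 1e-12, n = 1e-6),
    N  = c(eta = 1e-12),
    HB = c(sigma_y = 0, K = 1e-12, n = 1e-6))

  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 500)
  w <- 1 / stress
  theta <- theta0
  for (pass in 1:3) {
    ans <- minpack.lm::nls.lm(par = theta, lower = lower,
                              fn = constitutive_residual,
                              jac = constitutive_jacobian,
                              kind = kind, rate = rate, stress = stress, w = w,
                              control = ctrl)
    theta <- ans$par
    w <- 1 / pmax(model_stress(list(kind = kind, pars = theta), rate), 1e-12)
  }
  converged <- ans$info %in% 1:4
  J <- constitutive_jacobian(theta, kind, rate, stress, w)
  dof <- max(length(rate) - length(theta), 1L)
  sig2 <- sum(ans$fvec^2) / dof
  JtJ <- crossprod(J)
  se <- tryCatch(sqrt(pmax(diag(solve(JtJ)) * sig2, 0)),
                 error = function(e) rep(NA_real_, length(theta)))
  names(se) <- names(theta)

  fit <- structure(list(kind = kind, pars = theta, se = se,
                        converged = converged,
                        residual_norm = sqrt(sum(ans$fvec^2))),
                   class = "constitutive_fit")
  if (kind == "HB") {
    fit$coverage_ok <- (log10(max(rate) / min(rate)) >= 3)
  }
  fit
}

#' Replicate-level aggregation of fitted parameters
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of each
#' parameter across replicate fits of one constitutive model, the statistic
#' the model-selection cascade operates on.
#'
#' @param fits List of [constitutive_fit()] objects of a common `kind`
#'   (>= 2 fits).
#' @return List with `kind`, `n_replicates`, `mean` and `sd` (named numeric
#'   vectors over the model's parameters).
#' @export
aggregate_replicates <- function(fits) {
  if (length(fits) < 2L) {
    stop("aggregate_replicates: need >= 2 replicate fits (sd undefined otherwise)",
         call. = FALSE)
  }
  kinds <- vapply(fits, function(f) f$kind, character(1))
  if (length(unique(kinds)) != 1L) {
    stop("aggregate_replicates: fits mix model kinds", call. = FALSE)
  }
  P <- do.call(rbind, lapply(fits, function(f) f$pars))
  list(kind = kinds[[1]], n_replicates = length(fits),
       mean = colMeans(P), sd = apply(P, 2, stats::sd))
}

#' Constitutive model selection cascade
#'
#' Implements the replicate-dispersion selection rule: a model parameter whose
#' replicate standard deviation exceeds its replicate mean is statistically
#' insignificant, and the next simpler model is used. The cascade order is
#' HB -> PL -> N:
#' \enumerate{
#'   \item HB is kept iff `sd(sigma_y) < mean(sigma_y)` and `mean(sigma_y) > 0`;
#'     otherwise PL.
#'   \item If the PL rate index is near-Newtonian (`|n - 1| <= newtonian_gate`),
#'     the Newtonian model is also fitted and preferred iff its maximum relative
#'     deviation from the PL prediction over the measured rate range is at most
#'     `band_fraction`.
#' }
#'
#' @param aggregates Named list with elements `HB` and `PL` (and optionally
#'   `N`) as returned by [aggregate_replicates()].
#' @param curves List of replicate flow-curve data frames (used for the
#'   Newtonian comparison rate range and, when needed, Newtonian refits).
#' @param newtonian_gate Half-width of the near-Newtonian gate on `|n - 1|`
#'   (default 0.1).
#' @param band_fraction Relative deviation tolerance for preferring the
#'   Newtonian model (default 0.15).
#' @return A `selection_report` list: `temperature` (if found on the curves),
#'   `tried` (aggregates per model), `chosen`, `reasons` (rule firings, text
#'   codes), `sigma_y_sd_over_mean`, and `band_fraction`.
#' @export
select_model <- function(aggregates, curves, newtonian_gate = 0.1,
                         band_fraction = 0.15) {
  if (is.null(aggregates$HB) || is.null(aggregates$PL)) {
    stop("select_model: HB and PL aggregates are both required", call. = FALSE)
  }
  reasons <- character(0)
  tried <- aggregates

  mu_y <- aggregates$HB$mean[["sigma_y"]]
  sd_y <- aggregates$HB$sd[["sigma_y"]]
  ratio <- if (mu_y > 0) sd_y / mu_y else Inf
  if (mu_y > 0 && sd_y < mu_y) {
    chosen <- "HB"
    reasons <- c(reasons, "HB_kept:sd(sigma_y)<mean(sigma_y)")
  } else {
    chosen <- "PL"
    reasons <- c(reasons,
                 if (mu_y <= 0) "HB_rejected:mean(sigma_y)<=0"
                 else "HB_rejected:sd(sigma_y)>=mean(sigma_y)")
  }

  if (chosen == "PL") {
    n_pl <- aggregates$PL$mean[["n"]]
    if (abs(n_pl - 1) <= newtonian_gate) {
      reasons <- c(reasons, sprintf("N_gate:|n-1|=%.3g<=%.3g", abs(n_pl - 1), newtonian_gate))
      if (is.null(tried$N)) {
        nfits <- lapply(curves, fit_constitutive, kind = "N")
        tried$N <- aggregate_replicates(nfits)
      }
      rates <- sort(unique(unlist(lapply(curves, function(cv) cv$shear_rate_per_s))))
      pl_fit <- list(kind = "PL", pars = aggregates$PL$mean)
      n_fit <- list(kind = "N", pars = tried$N$mean)
      dev <- max(abs(model_stress(n_fit, rates) / model_stress(pl_fit, rates) - 1))
      if (dev <= band_fraction) {
        chosen <- "N"
        reasons <- c(reasons, sprintf("N_preferred:max_dev=%.3g<=%.3g", dev, band_fraction))
      } else {
        reasons <- c(reasons, sprintf("N_rejected:max_dev=%.3g>%.3g", dev, band_fraction))
      }
    } else {
      reasons <- c(reasons, sprintf("N_not_tried:|n-1|=%.3g>%.3g", abs(n_pl - 1), newtonian_gate))
    }
  }

  temperature <- if (length(curves) && !is.null(curves[[1]]$temperature_K)) {
    curves[[1]]$temperature_K[1]
  } else NA_real_
  structure(list(temperature = temperature, tried = tried, chosen = chosen,
                 reasons = reasons, sigma_y_sd_over_mean = ratio,
                 band_fraction = band_fraction),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Model selection at %s K: chosen %s\n",
              format(x$temperature), x$chosen))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Multiplicative prediction band around a constitutive fit
#'
#' The band `model * (1 -/+ fraction)` used to display agreement of observed
#' flow curves with a fitted model; also reports the fraction of supplied
#' observations falling inside.
#'
#' @param fit A [constitutive_fit()].
#' @param rates Shear rates, s^-1.
#' @param fraction Relative half-width (default 0.15).
#' @param observed Optional observed stresses at `rates` (Pa).
#' @return List with `rates`, `lower`, `upper`, `prediction`, and
#'   `inside_fraction` (NA when no observations supplied).
#' @export
prediction_band <- function(fit, rates, fraction = 0.15, observed = NULL) {
  pred <- model_stress(fit, rates)
  lower <- pred * (1 - fraction)
  upper <- pred * (1 + fraction)
  inside <- NA_real_
  if (!is.null(observed)) {
    inside <- mean(observed >= lower & observed <= upper)
  }
  list(rates = rates, prediction = pred, lower = lower, upper = upper,
       inside_fraction = inside)
}

#' Replicate-dispersion selection study at one temperature
#'
#' End-to-end selection exercise for the synthetic fluid: generate replicate
#' flow curves from the reference constitutive model accepted at the given
#' temperature (with the reported replicate dispersions and multiplicative
#' stress noise), fit HB and PL to every replicate, aggregate, and run the
#' selection cascade.
#'
#' @param temperature_K One of 283, 288, 295, 303, 313.
#' @param seed Integer RNG seed.
#' @param n_replicates Number of replicate curves (default 20, chosen so the
#'   dispersion rule has adequate power; see the methods vignette).
#' @param noise_cv Multiplicative stress noise CV (default 0.02).
#' @param rate_grid Shear-rate grid, s^-1 (default 20 log-spaced points over
#'   0.001-200).
#' @return The [select_model()] report, with the replicate aggregates in
#'   `$tried`.
#' @export
run_selection_study <- function(temperature_K, seed = 1L, n_replicates = 20L,
                                noise_cv = 0.02,
                                rate_grid = default_rate_grid()) {
  tab <- kc_flow_models()
  row <- tab[tab$temperature_K == temperature_K & tab$chosen, ]
  if (nrow(row) != 1L) {
    stop("no accepted reference model at ", temperature_K, " K", call. = FALSE)
  }
  ref <- kc_flow_row(temperature_K, row$kind)
  curves <- generate_flow_curve(
    model = list(kind = ref$kind, pars = ref$pars),
    rate_grid = rate_grid, noise_cv = noise_cv,
    replicate_dispersion = ref$sds, n_replicates = n_replicates,
    temperature_K = temperature_K, seed = seed)
  hb <- lapply(curves, fit_constitutive, kind = "HB")
  pl <- lapply(curves, fit_constitutive, kind = "PL")
  select_model(list(HB = aggregate_replicates(hb), PL = aggregate_replicates(pl)),
               curves)
}

#' Default flow-curve shear-rate grid
#'
#' 20 logarithmically spaced shear rates over 0.001-200 s^-1, the stepped-flow
#' protocol emulated by the synthetic flow curves (wide enough to identify a
#' small yield stress at the low end).
#'
#' @param n Number of points.
#' @param min_rate,max_rate Range, s^-1.
#' @return Numeric vector of rates, s^-1.
#' @export
default_rate_grid <- function(n = 20L, min_rate = 1e-3, max_rate = 200) {
  exp(seq(log(min_rate), log(max_rate), length.out = n))
}
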