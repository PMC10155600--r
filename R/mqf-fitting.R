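#' @name mqf_fitting
#' @title Sequential fitting of MQF build-up curves
#' @description
#' The analysis protocol fits the DQF-MA curve first - it depends on the
#' smaller parameter set (C0, nu_eff, R2fast) - and then fits the companion
#' TQF curve with nu_eff and R2fast frozen at the DQF estimates, so only
#' (C1, R2slow) remain adjustable. A TQF fit never re-estimates the frozen
#' parameters; the order is part of the method.
NULL

dqf_resid <- function(theta, tau, y) {
  theta[[1]] * sin(2 * pi * theta[[2]] * tau) * exp(-theta[[3]] * tau) - y
}

dqf_jac <- function(theta, tau, y) {
  s <- sin(2 * pi * theta[[2]] * tau)
  cc <- cos(2 * pi * theta[[2]] * tau)
  e <- exp(-theta[[3]] * tau)
  cbind(C0 = s * e,
        nu_eff = theta[[1]] * 2 * pi * tau * cc * e,
        R2fast = -theta[[1]] * tau * s * e)
}

tqf_constr_resid <- function(theta, tau, y, nu_eff, R2fast) {
  theta[[1]] * (exp(-theta[[2]] * tau) -
                  cos(2 * pi * nu_eff * tau) * exp(-R2fast * tau)) - y
}

tqf_constr_jac <- function(theta, tau, y, nu_eff, R2fast) {
  es <- exp(-theta[[2]] * tau)
  g <- es - cos(2 * pi * nu_eff * tau) * exp(-R2fast * tau)
  cbind(C1 = g, R2slow = -theta[[1]] * tau * es)
}

# free TQF model (presence detection only): theta = (C1, nu_eff, R2fast, R2slow)
tqf_free_resid <- function(theta, tau, y) {
  theta[[1]] * (exp(-theta[[4]] * tau) -
                  cos(2 * pi * theta[[2]] * tau) * exp(-theta[[3]] * tau)) - y
}

# decay-rate start from the log-linear tail of the rectified envelope
estimate_decay_start <- function(tau, y) {
  env <- rev(cummax(rev(abs(y))))
  keep <- env > 0.05 * max(env) & env > 0
  if (sum(keep) >= 3) {
    sl <- tryCatch(stats::coef(stats::lm(log(env[keep]) ~ tau[keep]))[[2]],
                   error = function(e) NA_real_)
    if (is.finite(sl) && sl < 0) return(min(max(-sl, 5), 2000))
  }
  100
}

new_mqf_fit <- function(filter_kind, params, se, covariance, converged,
                        residual_norm, status = "ok",
                        condition = c(temperature_K = NA_real_,
                                      shear_rate_per_s = NA_real_),
                        fixed = NULL) {
  structure(list(filter_kind = filter_kind, params = params, se = se,
                 covariance = covariance, converged = converged,
                 residual_norm = residual_norm, status = status,
                 condition = condition, fixed = fixed),
            class = "mqf_fit")
}

#' @export
print.mqf_fit <- function(x, ...) {
  cat(sprintf("%s fit [%s]:\n", x$filter_kind, x$status))
  if (x$status == "ok") {
    for (nm in names(x$params)) {
      cat(sprintf("  %s = %.5g +/- %.3g\n", nm, x$params[[nm]],
                  if (!is.null(x$se)) x$se[[nm]] else NA))
    }
    if (!is.null(x$fixed)) {
      cat("  fixed: ", paste(sprintf("%s = %.5g", names(x$fixed), x$fixed),
                             collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Fit the DQF-MA build-up model
#'
#' Least-squares estimation of (C0, nu_eff, R2fast) from a DQF-MA build-up
#' curve by Levenberg-Marquardt with analytic Jacobian and a multi-start over
#' the coupling: the argmax-based estimate `1/(4 tau*)` (tau* the location of
#' the largest rectified amplitude) plus five log-spaced values over
#' 20-400 Hz, each crossed with several decay-rate starts, with C0 profiled
#' linearly at each start. The coupling is bounded above by the tau grid's
#' Nyquist frequency `1/(2 min(diff(tau)))`: higher frequencies are
#' unidentifiable aliases of the sampled oscillation.
#' Standard errors follow the SNR-based procedure of
#' [estimate_errors()]. Deterministic given the curve and the start set.
#'
#' @param curve A `buildup_curve` with `filter_kind = "DQF_MA"` and at least
#'   6 tau points.
#' @param nu_starts Optional numeric vector of coupling starts, Hz
#'   (overrides the default strategy).
#' @return An `mqf_fit` with `params` (C0, nu_eff, R2fast), `se`,
#'   `covariance`, `converged`, `residual_norm` and `status` (`"ok"` or
#'   `"no_signal"` for an all-zero curve; non-convergence over all starts is
#'   a flagged failure, never a silent default).
#' @export
fit_dqf <- function(curve, nu_starts = NULL) {
  stopifnot(inherits(curve, "buildup_curve"))
  if (curve$filter_kind != "DQF_MA") {
    stop("fit_dqf expects a DQF_MA curve", call. = FALSE)
  }
  tau <- curve$tau; y <- curve$amplitude
  if (length(tau) < 6L) stop("fit_dqf: need >= 6 tau points", call. = FALSE)
  cond <- c(temperature_K = curve$temperature_K,
            shear_rate_per_s = curve$shear_rate_per_s)
  if (all(y == 0)) {
    return(new_mqf_fit("DQF_MA", c(C0 = 0, nu_eff = NA_real_, R2fast = NA_real_),
                       NULL, NULL, FALSE, 0, status = "no_signal",
                       condition = cond))
  }
  # couplings beyond the grid's Nyquist frequency are unidentifiable aliases
  nu_max <- 1 / (2 * min(diff(tau)))
  if (is.null(nu_starts)) {
    tau_star <- tau[which.max(abs(y))]
    nu_starts <- c(1 / (4 * tau_star), exp(seq(log(20), log(400), length.out = 5)))
  }
  nu_starts <- pmin(nu_starts, 0.99 * nu_max)
  r_starts <- unique(c(estimate_decay_start(tau, y), 60, 150))
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 1000)
  best <- NULL
  for (nu0 in nu_starts) for (r0 in r_starts) {
    g <- sin(2 * pi * nu0 * tau) * exp(-r0 * tau)
    den <- sum(g * g)
    c00 <- if (den > 0) sum(y * g) / den else max(abs(y))
    ans <- tryCatch(
      minpack.lm::nls.lm(par = c(C0 = c00, nu_eff = nu0, R2fast = r0),
                         lower = c(-Inf, 0, 0), upper = c(Inf, nu_max, 1e4),
                         fn = dqf_resid, jac = dqf_jac, tau = tau, y = y,
                         control = ctrl),
      error = function(e) NULL)
    if (is.null(ans)) next
    ssr <- sum(ans$fvec ^ 2)
    if (is.null(best) || ssr < best$ssr) best <- list(ans = ans, ssr = ssr)
  }
  if (is.null(best)) {
    return(new_mqf_fit("DQF_MA", c(C0 = NA_real_, nu_eff = NA_real_,
                                   R2fast = NA_real_),
                       NULL, NULL, FALSE, NA_real_, status = "failed",
                       condition = cond))
  }
  theta <- best$ans$par
  converged <- best$ans$info %in% 1:4
  fit <- new_mqf_fit("DQF_MA", theta, NULL, NULL, converged,
                     sqrt(best$ssr),
                     status = if (converged) "ok" else "failed",
                     condition = cond)
  if (converged) {
    err <- estimate_errors(fit, curve)
    fit$se <- err$se; fit$covariance <- err$covariance
    if (err$singular) fit$status <- "unidentifiable"
  }
  fit
}

#' Fit the TQF build-up model with frozen coupling and fast rate
#'
#' The second stage of the sequential protocol: nu_eff and R2fast from a
#' converged companion DQF-MA fit at the same condition enter as
#' non-adjustable coefficients, and only (C1, R2slow) are estimated. By
#' default the uncertainty of the frozen coefficients is not propagated into
#' the R2slow standard error (they are treated as exact); set
#' `propagate_fixed = TRUE` for a delta-method sensitivity variant using the
#' DQF covariance.
#'
#' @param curve A `buildup_curve` with `filter_kind = "TQF"`.
#' @param fixed Either a converged DQF-MA `mqf_fit` or a named vector/list
#'   with `nu_eff` (Hz) and `R2fast` (s^-1).
#' @param propagate_fixed Propagate the DQF parameter covariance into the
#'   reported standard errors (requires `fixed` to be an `mqf_fit`).
#' @return An `mqf_fit` with `params` (C1, R2slow) and the frozen values in
#'   `$fixed`.
#' @export
fit_tqf_constrained <- function(curve, fixed, propagate_fixed = FALSE) {
  stopifnot(inherits(curve, "buildup_curve"))
  if (curve$filter_kind != "TQF") {
    stop("fit_tqf_constrained expects a TQF curve", call. = FALSE)
  }
  dqf_fit <- NULL
  if (inherits(fixed, "mqf_fit")) {
    dqf_fit <- fixed
    if (dqf_fit$status != "ok" || !dqf_fit$converged) {
      stop("fit_tqf_constrained: companion DQF-MA fit did not converge; ",
           "the sequential order requires a valid DQF fit first", call. = FALSE)
    }
    fixed <- c(nu_eff = dqf_fit$params[["nu_eff"]],
               R2fast = dqf_fit$params[["R2fast"]])
  }
  fixed <- unlist(fixed)[c("nu_eff", "R2fast")]
  if (anyNA(fixed)) {
    stop("fit_tqf_constrained: missing frozen nu_eff/R2fast", call. = FALSE)
  }
  tau <- curve$tau; y <- curve$amplitude
  cond <- c(temperature_K = curve$temperature_K,
            shear_rate_per_s = curve$shear_rate_per_s)
  if (all(y == 0)) {
    return(new_mqf_fit("TQF", c(C1 = 0, R2slow = NA_real_), NULL, NULL, FALSE,
                       0, status = "no_signal", condition = cond,
                       fixed = fixed))
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 1000)
  best <- NULL
  for (r0 in c(10, 30, 60, 120)) {
    g <- exp(-r0 * tau) - cos(2 * pi * fixed[["nu_eff"]] * tau) *
      exp(-fixed[["R2fast"]] * tau)
    den <- sum(g * g)
    c10 <- if (den > 0) sum(y * g) / den else max(abs(y))
    ans <- tryCatch(
      minpack.lm::nls.lm(par = c(C1 = c10, R2slow = r0),
                         lower = c(-Inf, 0), upper = c(Inf, 1e4),
                         fn = tqf_constr_resid, jac = tqf_constr_jac,
                         tau = tau, y = y,
                         nu_eff = fixed[["nu_eff"]], R2fast = fixed[["R2fast"]],
                         control = ctrl),
      error = function(e) NULL)
    if (is.null(ans)) next
    ssr <- sum(ans$fvec ^ 2)
    if (is.null(best) || ssr < best$ssr) best <- list(ans = ans, ssr = ssr)
  }
  if (is.null(best)) {
    return(new_mqf_fit("TQF", c(C1 = NA_real_, R2slow = NA_real_), NULL, NULL,
                       FALSE, NA_real_, status = "failed", condition = cond,
                       fixed = fixed))
  }
  converged <- best$ans$info %in% 1:4
  fit <- new_mqf_fit("TQF", best$ans$par, NULL, NULL, converged,
                     sqrt(best$ssr),
                     status = if (converged) "ok" else "failed",
                     condition = cond, fixed = fixed)
  if (converged) {
    err <- estimate_errors(fit, curve,
                           dqf_fit = if (propagate_fixed) dqf_fit else NULL)
    fit$se <- err$se; fit$covariance <- err$covariance
    if (err$singular) fit$status <- "unidentifiable"
  }
  fit
}

#' Sequential DQF-MA then constrained TQF fit of a curve pair
#'
#' @param dqf_curve,tqf_curve Companion build-up curves at one condition.
#' @param ... Passed to [fit_dqf()].
#' @return List with elements `dqf` and `tqf` (`mqf_fit` objects; `tqf` is
#'   `NULL` when the DQF stage yields no usable signal).
#' @export
fit_mqf_pair <- function(dqf_curve, tqf_curve, ...) {
  d <- fit_dqf(dqf_curve, ...)
  t <- if (d$status == "ok" && d$converged) {
    fit_tqf_constrained(tqf_curve, d)
  } else NULL
  list(dqf = d, tqf = t)
}

# model Jacobian of a fit at its optimum, in the fitted parameters only
fit_jacobian <- function(fit, curve) {
  tau <- curve$tau
  if (fit$filter_kind == "DQF_MA") {
    dqf_jac(fit$params, tau, curve$amplitude)
  } else {
    tqf_constr_jac(fit$params, tau, curve$amplitude,
                   nu_eff = fit$fixed[["nu_eff"]], R2fast = fit$fixed[["R2fast"]])
  }
}

#' SNR-based standard errors of an MQF fit
#'
#' Standard errors are propagated from the per-point noise level:
#' `SE = sigma * sqrt(diag((J' J)^-1))`, with `J` the analytic model Jacobian
#' at the optimum and `sigma` the per-point noise standard deviation - taken
#' from the curve's SNR metadata when known, otherwise from the residual
#' variance. A singular normal matrix is flagged as unidentifiable.
#'
#' @param fit A converged `mqf_fit`.
#' @param curve The fitted `buildup_curve`.
#' @param dqf_fit Optional companion DQF-MA fit; when supplied for a
#'   constrained TQF fit, the frozen-parameter covariance is propagated by
#'   the delta method instead of being treated as exact.
#' @return List with `se` (named), `covariance`, `sigma`, `singular`.
#' @export
estimate_errors <- function(fit, curve, dqf_fit = NULL) {
  if (!fit$converged) stop("estimate_errors: fit did not converge", call. = FALSE)
  J <- fit_jacobian(fit, curve)
  sigma <- curve$noise_sigma
  if (is.null(sigma) || !is.finite(sigma)) {
    r <- mqf_fit_residuals(fit, curve)
    sigma <- sqrt(sum(r ^ 2) / max(length(r) - length(fit$params), 1L))
  }
  JtJ <- crossprod(J)
  inv <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(inv)) {
    return(list(se = stats::setNames(rep(NA_real_, length(fit$params)),
                                     names(fit$params)),
                covariance = NULL, sigma = sigma, singular = TRUE))
  }
  covariance <- inv * sigma ^ 2
  if (!is.null(dqf_fit) && fit$filter_kind == "TQF" &&
      !is.null(dqf_fit$covariance)) {
    # delta method: d model / d (nu_eff, R2fast) at the optimum
    tau <- curve$tau
    c1 <- fit$params[["C1"]]; nu <- fit$fixed[["nu_eff"]]
    rf <- fit$fixed[["R2fast"]]
    ef <- exp(-rf * tau)
    dnu <- c1 * 2 * pi * tau * sin(2 * pi * nu * tau) * ef
    drf <- c1 * tau * cos(2 * pi * nu * tau) * ef
    Jf <- cbind(nu_eff = dnu, R2fast = drf)
    Sf <- dqf_fit$covariance[c("nu_eff", "R2fast"), c("nu_eff", "R2fast")]
    A <- -inv %*% crossprod(J, Jf)    # d theta / d fixed
    covariance <- covariance + A %*% Sf %*% t(A)
  }
  dimnames(covariance) <- list(names(fit$params), names(fit$params))
  list(se = sqrt(pmax(diag(covariance), 0)), covariance = covariance,
       sigma = sigma, singular = FALSE)
}

mqf_fit_residuals <- function(fit, curve) {
  if (fit$filter_kind == "DQF_MA") {
    dqf_resid(fit$params, curve$tau, curve$amplitude)
  } else {
    tqf_constr_resid(fit$params, curve$tau, curve$amplitude,
                     nu_eff = fit$fixed[["nu_eff"]],
                     R2fast = fit$fixed[["R2fast"]])
  }
}

#' Presence test for a multiple-quantum signal
#'
#' Fits the appropriate forward model (free parameters for both filters) and
#' declares a signal when the peak amplitude of the fitted model exceeds
#' `k` noise standard deviations (default k = 3, the conventional detection
#' threshold). Absence-of-signal conditions - no shear, or temperatures at
#' and above the helix-coil cutoff - produce pure-noise curves that fail this
#' test.
#'
#' @param curve A `buildup_curve` (DQF_MA or TQF).
#' @param k Detection threshold in noise standard deviations.
#' @return List with `signal` (`TRUE`/`FALSE`), `peak_amplitude`, `sigma`,
#'   `threshold`.
#' @export
detect_mqf_presence <- function(curve, k = 3) {
  tau <- curve$tau; y <- curve$amplitude
  sigma <- curve$noise_sigma
  if (is.null(sigma) || !is.finite(sigma) || sigma <= 0) {
    sigma <- stats::sd(diff(y)) / sqrt(2)   # noise floor from first differences
  }
  if (all(y == 0)) {
    return(list(signal = FALSE, peak_amplitude = 0, sigma = sigma,
                threshold = k * sigma))
  }
  peak <- if (curve$filter_kind == "DQF_MA") {
    f <- fit_dqf(curve)
    if (f$status != "ok") 0 else max(abs(dqf_resid(f$params, tau, 0 * tau)))
  } else {
    ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 500)
    nu_max <- 1 / (2 * min(diff(tau)))
    best <- NULL
    for (nu0 in c(0, 50, 150, 300)) for (rs0 in c(20, 60)) {
      ans <- tryCatch(
        minpack.lm::nls.lm(par = c(C1 = max(abs(y)), nu_eff = min(nu0, 0.99 * nu_max),
                                   R2fast = 150, R2slow = rs0),
                           lower = c(-Inf, 0, 0, 0), upper = c(Inf, nu_max, 1e4, 1e4),
                           fn = tqf_free_resid, tau = tau, y = y, control = ctrl),
        error = function(e) NULL)
      if (is.null(ans)) next
      if (is.null(best) || sum(ans$fvec ^ 2) < best$ssr) {
        best <- list(ans = ans, ssr = sum(ans$fvec ^ 2))
      }
    }
    if (is.null(best)) 0 else {
      max(abs(tqf_free_resid(best$ans$par, tau, 0 * tau)))
    }
  }
  list(signal = peak > k * sigma, peak_amplitude = peak, sigma = sigma,
       threshold = k * sigma)
}

#' Shear-rate dependence of the coupling and slow rate
#'
#' Weighted linear regression of the residual quadrupolar coupling on shear
#' rate (weights 1/SE^2 when standard errors are available), together with a
#' two-sided flatness test of the R2slow-versus-rate slope - the molecular
#' signature that shear aligns the helices (coupling grows linearly) without
#' changing the slow relaxation channel.
#'
#' @param results Either a list of converged `mqf_fit` pairs or a data frame
#'   with columns `shear_rate_per_s`, `nu_eff_Hz`, `R2slow_per_s` and
#'   optionally `nu_eff_se_Hz`, `R2slow_se_per_s`. At least 3 shear rates.
#' @return List of class `shear_dependence`: `nu_slope` (Hz s), `nu_intercept`
#'   (Hz), `slope_error`, `intercept_error`, `r2slow_slope`,
#'   `r2slow_flatness_p` (two-sided p-value that the R2slow slope is zero),
#'   `n`.
#' @export
fit_shear_dependence <- function(results) {
  df <- as_mqf_series(results)
  if (nrow(df) < 3L) {
    stop("fit_shear_dependence: need >= 3 shear rates", call. = FALSE)
  }
  w_nu <- if (!is.null(df$nu_eff_se_Hz) && all(is.finite(df$nu_eff_se_Hz)) &&
              all(df$nu_eff_se_Hz > 0)) 1 / df$nu_eff_se_Hz ^ 2 else NULL
  m_nu <- stats::lm(nu_eff_Hz ~ shear_rate_per_s, data = df, weights = w_nu)
  s_nu <- summary(m_nu)$coefficients
  w_rs <- if (!is.null(df$R2slow_se_per_s) && all(is.finite(df$R2slow_se_per_s)) &&
              all(df$R2slow_se_per_s > 0)) 1 / df$R2slow_se_per_s ^ 2 else NULL
  m_rs <- stats::lm(R2slow_per_s ~ shear_rate_per_s, data = df, weights = w_rs)
  s_rs <- summary(m_rs)$coefficients
  structure(list(nu_slope = s_nu["shear_rate_per_s", "Estimate"],
                 nu_intercept = s_nu["(Intercept)", "Estimate"],
                 slope_error = s_nu["shear_rate_per_s", "Std. Error"],
                 intercept_error = s_nu["(Intercept)", "Std. Error"],
                 r2slow_slope = s_rs["shear_rate_per_s", "Estimate"],
                 r2slow_flatness_p = s_rs["shear_rate_per_s", "Pr(>|t|)"],
                 n = nrow(df)),
            class = "shear_dependence")
}

as_mqf_series <- function(results) {
  if (is.data.frame(results)) return(results)
  rows <- lapply(results, function(pair) {
    d <- pair$dqf; t <- pair$tqf
    data.frame(
      temperature_K = d$condition[["temperature_K"]],
      shear_rate_per_s = d$condition[["shear_rate_per_s"]],
      nu_eff_Hz = d$params[["nu_eff"]],
      nu_eff_se_Hz = if (!is.null(d$se)) d$se[["nu_eff"]] else NA_real_,
      R2fast_per_s = d$params[["R2fast"]],
      R2fast_se_per_s = if (!is.null(d$se)) d$se[["R2fast"]] else NA_real_,
      R2slow_per_s = if (!is.null(t)) t$params[["R2slow"]] else NA_real_,
      R2slow_se_per_s = if (!is.null(t) && !is.null(t$se)) t$se[["R2slow"]] else NA_real_)
  })
  do.call(rbind, rows)
}

#' Arrhenius analysis of relaxation times and coupling
#'
#' Linear fits of `ln T2fast`, `ln T2slow` (T2 = 1/R2) and `ln nu_eff`
#' against inverse temperature, with slope/intercept standard errors and a
#' per-point flag marking whether the back-transformed observation lies
#' within a relative band (default 5%) of the fitted line.
#'
#' @param series Data frame with columns `temperature_K`, `R2fast_per_s`,
#'   `R2slow_per_s`, `nu_eff_Hz` (>= 3 temperatures, all rates and couplings
#'   strictly positive), or a list of fit pairs as in
#'   [fit_shear_dependence()].
#' @param band_fraction Relative half-width of the deviation band.
#' @return A named list of `arrhenius_result` objects (`ln_T2fast`,
#'   `ln_T2slow`, `ln_nu_eff`), each with `slope` (K), `intercept`,
#'   `slope_error`, `intercept_error`, `band_fraction`, and a `points` data
#'   frame with `inv_T`, `observed`, `predicted`, `within_band`.
#' @export
arrhenius_analysis <- function(series, band_fraction = 0.05) {
  df <- as_mqf_series(series)
  df <- df[stats::complete.cases(df[, c("temperature_K", "R2fast_per_s",
                                        "R2slow_per_s", "nu_eff_Hz")]), ]
  if (nrow(df) < 3L) stop("arrhenius_analysis: need >= 3 temperatures", call. = FALSE)
  if (any(df$R2fast_per_s <= 0) || any(df$R2slow_per_s <= 0) ||
      any(df$nu_eff_Hz <= 0)) {
    stop("arrhenius_analysis: rates and couplings must be > 0", call. = FALSE)
  }
  quantities <- list(ln_T2fast = log(1 / df$R2fast_per_s),
                     ln_T2slow = log(1 / df$R2slow_per_s),
                     ln_nu_eff = log(df$nu_eff_Hz))
  inv_T <- 1 / df$temperature_K
  lapply(quantities, function(lny) {
    m <- stats::lm(lny ~ inv_T)
    s <- summary(m)$coefficients
    pred <- stats::fitted(m)
    structure(list(slope = s["inv_T", "Estimate"],
                   intercept = s["(Intercept)", "Estimate"],
                   slope_error = s["inv_T", "Std. Error"],
                   intercept_error = s["(Intercept)", "Std. Error"],
                   band_fraction = band_fraction,
                   points = data.frame(
                     inv_T = inv_T, observed = exp(lny), predicted = exp(pred),
                     within_band = abs(exp(lny) / exp(pred) - 1) <= band_fraction)),
              class = "arrhenius_result")
  })
}
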