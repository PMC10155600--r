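#' Parameter set for multiple-quantum-filtered sodium build-up curves
#'
#' Bundles the five quantities that determine the shape of spin-3/2 sodium
#' DQF-MA and TQF build-up curves in a slowly tumbling, partially aligned
#' environment: the two filter amplitudes, the residual quadrupolar coupling,
#' and the fast/slow transverse relaxation rates.
#'
#' @param C0 DQF-MA amplitude (arbitrary units).
#' @param C1 TQF amplitude (arbitrary units).
#' @param nu_eff Residual quadrupolar coupling, in Hz (cyclic frequency).
#'   Zero in an isotropic environment; non-zero only under net alignment.
#' @param R2fast Fast transverse relaxation rate, s^-1 (outer transitions).
#' @param R2slow Slow transverse relaxation rate, s^-1 (central transition).
#'   Equal to `R2fast` when motional averaging is fast (mono-exponential
#'   relaxation).
#'
#' @return An object of class `mqf_params` (a named list).
#' @examples
#' p <- mqf_params(C0 = 1, C1 = 1, nu_eff = 188, R2fast = 153, R2slow = 46)
#' @export
mqf_params <- function(C0 = 1, C1 = 1, nu_eff = 0, R2fast = 0, R2slow = R2fast) {
  p <- list(C0 = as.numeric(C0), C1 = as.numeric(C1),
            nu_eff = as.numeric(nu_eff),
            R2fast = as.numeric(R2fast), R2slow = as.numeric(R2slow))
  validate_mqf_params(p)
  structure(p, class = "mqf_params")
}

validate_mqf_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("mqf_params: all fields must be finite scalars (bad: ",
         paste(names(p)[!num], collapse = ", "), ")", call. = FALSE)
  }
  if (p$nu_eff < 0) stop("mqf_params: nu_eff must be >= 0", call. = FALSE)
  if (p$R2fast < 0 || p$R2slow < 0) {
    stop("mqf_params: relaxation rates must be >= 0", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.mqf_params <- function(x, ...) {
  cat(sprintf(
    "MQF parameters: C0 = %.4g, C1 = %.4g, nu_eff = %.4g Hz, R2fast = %.4g /s, R2slow = %.4g /s\n",
    x$C0, x$C1, x$nu_eff, x$R2fast, x$R2slow))
  invisible(x)
}

#' Grid of multiple-quantum creation times
#'
#' The creation (evolution) time tau is the delay during which single-quantum
#' coherence converts into rank-2/3 coherences; build-up curves sample the
#' filtered signal amplitude on such a grid. The default mirrors the
#' acquisition used throughout this package's study conditions: 45 linearly
#' spaced increments. The default span (0.2-18 ms) covers at least two
#' oscillation periods at couplings of 110-215 Hz and at least two decay
#' constants at fast rates of 40-170 s^-1.
#'
#' @param n Number of increments (default 45, must be >= 2).
#' @param tau_min,tau_max Range of tau, in seconds.
#' @param values Optional explicit vector of tau values (seconds, strictly
#'   increasing, non-negative); overrides the other arguments.
#' @return Numeric vector of class `tau_grid`, in seconds.
#' @export
tau_grid <- function(n = 45L, tau_min = 2e-4, tau_max = 18e-3, values = NULL) {
  v <- if (is.null(values)) seq(tau_min, tau_max, length.out = n) else as.numeric(values)
  if (length(v) < 2L) stop("tau_grid: need at least 2 tau values", call. = FALSE)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("tau_grid: tau values must be finite and non-negative", call. = FALSE)
  }
  if (any(diff(v) <= 0)) stop("tau_grid: tau values must be strictly increasing", call. = FALSE)
  structure(v, class = c("tau_grid", "numeric"))
}

as_tau_grid <- function(tau) {
  if (inherits(tau, "tau_grid")) tau else tau_grid(values = tau)
}

#' DQF-MA build-up signal
#'
#' Closed-form forward model for the double-quantum-filtered magic-angle
#' build-up curve of spin-3/2 sodium:
#' \deqn{S(\tau) = C_0 \sin(2\pi\nu_{\mathrm{eff}}\tau)\, e^{-R_2^{fast}\tau}.}
#' The rank-2 coherence selected by the magic-angle filter is created only by
#' a residual quadrupolar coupling, so the signal vanishes identically when
#' `nu_eff = 0` (no macroscopic alignment) and at `tau = 0`.
#'
#' @param params An [mqf_params()] object.
#' @param tau A [tau_grid()] or numeric vector of creation times (s).
#' @return Numeric vector of signal amplitudes (a.u.), one per tau.
#' @seealso [tqf_signal()]
#' @export
dqf_ma_signal <- function(params, tau) {
  params <- as_mqf_params(params)
  tau <- as_tau_grid(tau)
  params$C0 * sin(2 * pi * params$nu_eff * tau) * exp(-params$R2fast * tau)
}

#' TQF build-up signal
#'
#' Closed-form forward model for the triple-quantum-filtered build-up curve:
#' \deqn{S(\tau) = C_1 \left[ e^{-R_2^{slow}\tau} -
#'   \cos(2\pi\nu_{\mathrm{eff}}\tau)\, e^{-R_2^{fast}\tau} \right].}
#' The rank-3 coherence is created either through the residual quadrupolar
#' coupling (alignment) or through biexponential relaxation (slow motion):
#' with `nu_eff = 0` the signal reduces to the biexponential difference
#' `C1 * (exp(-R2slow*tau) - exp(-R2fast*tau))`, and it vanishes identically
#' in the mono-exponential isotropic limit `nu_eff = 0, R2slow = R2fast`.
#'
#' @inheritParams dqf_ma_signal
#' @return Numeric vector of signal amplitudes (a.u.), one per tau.
#' @export
tqf_signal <- function(params, tau) {
  params <- as_mqf_params(params)
  tau <- as_tau_grid(tau)
  params$C1 * (exp(-params$R2slow * tau) -
                 cos(2 * pi * params$nu_eff * tau) * exp(-params$R2fast * tau))
}

as_mqf_params <- function(params) {
  if (inherits(params, "mqf_params")) {
    validate_mqf_params(params)
    return(params)
  }
  if (is.list(params)) return(do.call(mqf_params, params))
  stop("expected an mqf_params object", call. = FALSE)
}

# Forward model dispatch on filter kind ("DQF_MA" or "TQF").
mqf_forward <- function(params, tau, filter_kind) {
  switch(match.arg(filter_kind, c("DQF_MA", "TQF")),
         DQF_MA = dqf_ma_signal(params, tau),
         TQF = tqf_signal(params, tau))
}
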