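---
title: "Methods: sequential MQF fitting and the synthetic carrageenan fluid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential MQF fitting and the synthetic carrageenan fluid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheomqf)
```

## The physical problem

A dilute (0.5%) aqueous kappa-carrageenan fluid carries its own sodium
counter-ions. Sodium-23 is a spin-3/2 nucleus: when the polymer helices are
driven into a macroscopically aligned phase by shear, the ions experience a
residual quadrupolar coupling `nu_eff` (Hz), and when molecular motion is
slow their transverse relaxation splits into a fast rate `R2fast` and a slow
rate `R2slow` (s^-1). Multiple-quantum filters isolate exactly these
signatures:

* the **DQF-MA** (double-quantum-filtered, magic-angle) build-up curve
  exists only under a non-zero coupling, i.e. only in an aligned phase,

  $$S_{DQF}(\tau) = C_0 \sin(2\pi\nu_{eff}\tau)\, e^{-R_2^{fast}\tau};$$

* the **TQF** (triple-quantum-filtered) curve survives either through the
  coupling or through biexponential relaxation,

  $$S_{TQF}(\tau) = C_1\left[e^{-R_2^{slow}\tau} -
      \cos(2\pi\nu_{eff}\tau)\, e^{-R_2^{fast}\tau}\right].$$

`nu_eff` is a cyclic frequency in Hz, so the trigonometric arguments carry
the `2*pi` factor explicitly. Both closed forms vanish at `tau = 0`; the
TQF form reduces to a biexponential difference at `nu_eff = 0` and vanishes
identically in the mono-exponential isotropic limit. These structural facts
are the package's first line of tests.

The companion bulk-rheology workflow characterises the same fluid
macroscopically: Herschel-Bulkley / power-law / Newtonian flow-curve fits
with a replicate-dispersion selection cascade, the linear viscoelastic
region (LVR), the storage/loss modulus crossover across the helix-coil
transition, and the Cox-Merz comparison of complex and steady viscosity.

## Sequential constrained fitting

The DQF-MA curve depends on (C0, nu_eff, R2fast) only, so it is fitted
first; the TQF curve is then fitted with `nu_eff` and `R2fast` frozen as
non-adjustable coefficients, leaving (C1, R2slow). `fit_tqf_constrained()`
refuses to run without a converged companion DQF fit: the order is part of
the method, and a TQF fit never re-estimates the frozen parameters.

Numerical choices, all visible in the function documentation:

* Levenberg-Marquardt (`minpack.lm::nls.lm`) with analytic Jacobians;
  objective tolerances `ftol = ptol = 1e-12`, at most 1000 iterations per
  start. Noiseless curves are recovered to better than 1e-6 relative.
* Multi-start over the coupling: the argmax-based estimate
  `1/(4 tau*)` plus five log-spaced starts over 20-400 Hz, crossed with
  decay-rate starts from the log-linear tail of the rectified envelope plus
  two fixed values; the amplitude is profiled linearly at every start. The
  lowest sum of squares wins; ties cannot occur in practice and the first
  minimum found is kept.
* The coupling is bounded above by the tau grid's Nyquist frequency
  `1/(2 min(diff(tau)))`. Higher frequencies are aliases of the sampled
  oscillation and occasionally produced spurious global minima on noisy
  curves before the bound was imposed.
* Degenerate inputs: an all-zero curve returns a `"no_signal"` outcome with
  the coupling undefined; failure of every start is a flagged failure,
  never a silent default.

Standard errors follow the signal-to-noise route: `SE = sigma *
sqrt(diag((J'J)^-1))` with `J` the analytic Jacobian at the optimum and
`sigma` the per-point noise, taken from the curve's SNR metadata when known
and from the residual variance otherwise. For the constrained TQF fit the
frozen coefficients are treated as exact by default, mirroring their
non-adjustable role; `propagate_fixed = TRUE` adds their covariance by the
delta method for sensitivity studies. Fit weighting is uniform per point,
matching the homoscedastic noise model below.

Presence of a multiple-quantum signal is declared when the peak amplitude
of the fitted model exceeds `k = 3` noise standard deviations - the
conventional 3-sigma detection choice; the acceptance suite measures a
false-positive rate of at most 1% over 1000 pure-noise curves.

Downstream series analyses are ordinary (weighted) linear regressions via
`stats::lm`: coupling versus shear rate (with a two-sided flatness test of
the `R2slow` slope), and `ln T2fast`, `ln T2slow`, `ln nu_eff` versus
inverse temperature with a 5% relative deviation band flag per point.

## Constitutive fitting and the selection cascade

Flow curves span more than five decades of shear rate with
constant-coefficient-of-variation noise, so `fit_constitutive()` uses
iteratively reweighted least squares: three Levenberg-Marquardt passes with
inverse-stress weights frozen within a pass and refreshed from the current
model between passes. Weights taken from the observations correlate with
the noise draw, and residual *ratios* differentiate the weights through the
objective; both bias scale parameters by O(cv^2), which the frozen-weight
estimating equation avoids (for the Newtonian model it reduces exactly to
the mean of per-point viscosities). The Herschel-Bulkley yield stress is
bounded below at zero; identifying a small yield stress further needs
low-rate coverage, so fits on ranges narrower than three decades carry a
`coverage_ok = FALSE` flag.

The selection cascade implements the replicate-dispersion rule with the
fixed order HB -> PL -> N (the order in which the models lose structure): a
yield stress whose replicate standard deviation reaches its replicate mean
is statistically insignificant and drops HB to PL; a power-law index within
`|n - 1| <= 0.1` opens the Newtonian gate (the threshold operationalises
"very close to one"; no sharper value is available), and the Newtonian
model is preferred when its predictions stay within 15% of the power-law
predictions over the measured rate range. Every rule firing is recorded as
a text code in the `selection_report`.

## What the synthetic generator emulates

No instrument data accompany the study this package re-implements, so the
synthetic module is a first-class, tested component that defines the study
conditions; all recovery claims are claims about these conditions.

* **Build-up curves**: forward model plus i.i.d. Gaussian noise,
  homoscedastic per curve, `sigma = max|signal| / SNR`, default SNR 20 and
  45 linearly spaced tau increments from 0.2 to 18 ms. The span covers at
  least two oscillation periods at couplings of 110-215 Hz and two decay
  constants at fast rates of 40-170 s^-1. When a null condition makes the
  forward model identically zero, the amplitude parameter replaces
  `max|signal|` as the noise reference so such curves still carry
  instrument noise.
* **Flow curves**: each replicate draws its constitutive parameters from
  Gaussian dispersion (the reported replicate standard deviations),
  truncated at the physical bounds, then applies 2% multiplicative stress
  noise on 20 log-spaced rates over 0.001-200 s^-1. The default of 20
  replicates comes from a design-time power analysis of the dispersion
  rule: with censored-at-zero yield estimates the probability of correctly
  rejecting a spurious yield stress is about 0.92 at 10 replicates and 0.97
  at 20. Selection studies generate each temperature's replicates from the
  constitutive model accepted at that temperature, so the cascade's job is
  to re-discover it.
* **Temperature behaviour**: a helix fraction
  `phi(T) = 1/(1 + exp((T - T_mid)/Delta_T))` drives storage and loss
  moduli (`G0' phi^4` and `G0'' phi^2 + eta(T) omega`), the steady
  viscosity `eta(T) = eta_high (1 + 115 phi^2)`, the rate index
  interpolating from 0.35 to 1, and the shear-induced coupling through a
  melt factor that reaches zero at 303 K. The storage-modulus scale is not
  a free parameter: it is solved analytically so the implied modulus
  crossover falls exactly at the configured 301.7 K. With the defaults
  (T_mid = 299 K, Delta_T = 3 K) the viscosity drops more than 100-fold
  from 283 to 313 K, and the complex and steady viscosities agree within
  10% from 305 K upward while disagreeing severalfold at 288 K - the
  calibration targets are these qualitative features, not a point-by-point
  trace of any figure.
* **Frequency sweeps** put the Cox-Merz baseline in the loss modulus
  (`G'' = eta_steady(omega) * omega`) and add the structural elastic
  contribution `eta* / eta = 1 + 1.2 phi^2`, so the rule fails in the
  entangled helix regime and holds above the transition.
* **Amplitude sweeps** use a plateau-decay modulus
  `G_p / (1 + (gamma/gamma_b)^2)` with `gamma_b` placed so the 5% departure
  from the plateau falls exactly at 20% strain. The LVR detector uses a 5%
  criterion on the storage modulus relative to the median of the first five
  points; the original analysis states only the outcome, not its
  criterion, and a stress-based criterion would be an equally defensible
  alternative.

Determinism: every generator takes an explicit integer seed
(`withr::with_seed`), identical configurations give byte-identical outputs,
and pipeline outputs embed the seed, package version and a hash of the
scientific settings.

What the generator deliberately does **not** emulate: raw spectra and
lineshapes, phase cycling, temperature-equilibration transients, rheometer
inertia (the high-frequency raw-phase artefact is noted in the original
data but not simulated), thixotropy, shear banding, or Couette gap
corrections. Passing recovery tests therefore demonstrate correctness of
the estimators under the stated noise model, not robustness to instrument
artefacts absent from it. Two further cautions: the temperature-sweep and
frequency-sweep moduli are separately calibrated phenomenological surfaces
rather than one consistent `G(omega, T)`; and the reported coupling at
298 K differs between the study's text (28 Hz) and its parameter table
(52 Hz) - the package treats the table as canonical and the generator must
not be used to adjudicate that discrepancy.

## Crossover, Cox-Merz and detectors

The modulus crossover is located by interpolating `log G' - log G''`
linearly in temperature between the bracketing grid points - moduli vary
exponentially through the transition, so interpolation in log space is the
numerically faithful choice; the detector agrees with the analytic
intersection of constructed log-linear moduli to 1e-6 relative. Multiple
crossings return the lowest with a flag. The Cox-Merz comparison
identifies rad/s with 1/s numerically, interpolates in log-log space over
the overlapping range only, and reports the maximum relative deviation
against a 10% tolerance; disjoint ranges are flagged undefined rather than
extrapolated.

## Problem sizes

The shipped test-suite and acceptance studies use: 50 seeds per MQF
recovery row at SNR 20 and 45 tau points; 100 seeds x 10-20 replicates x 20
rates for flow-curve recovery and selection; 1000 pure-noise curves for the
false-positive rate; 200 repeats for the Monte-Carlo validation of the
SNR-propagated standard errors (these match the empirical spread within
15%). These sizes put Monte-Carlo standard errors well below the reported
uncertainties of every recovered quantity while keeping the default run in
the low minutes on one core.

## Known limitations

* The DQF-MA/TQF closed forms are the standard single-quantum-to-rank-2/3
  transfer expressions for spin-3/2 under residual coupling and
  biexponential relaxation; scalar prefactor conventions differ across the
  literature and are absorbed into the arbitrary-unit amplitudes. The
  forward models are single swap-able functions should a different
  convention be needed.
* Global simultaneous DQF+TQF fitting is intentionally absent: the
  sequential protocol is the method under study.
* The helix-coil module is phenomenological. Its absolute modulus scale is
  a consequence of the crossover/viscosity coupling, not a measured value,
  and no relaxation-spectrum structure is modelled (the original
  frequency-sweep data did not support relaxation analysis either).
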