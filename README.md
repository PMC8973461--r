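# sirqmt

Voxelwise parameter mapping for **selective inversion recovery (SIR)
quantitative magnetization transfer MRI** — a fast, scriptable toolkit for
estimating myelin-sensitive tissue parameters from inversion recovery image
series acquired with reduced pre-delays.

SIR uses a low-power, on-resonance inversion that inverts the free-water
longitudinal magnetization while only partially saturating protons bound in
macromolecules (myelin). Exchange between the two pools during recovery makes
the signal biexponential in the inversion time, and fitting the coupled
two-pool model

$$\mathbf{M}_z(t_I, t_D) = \left[e^{A t_I} S (I - e^{A t_D}) + (I - e^{A t_I})\right] \mathbf{M}_0,\qquad
A = \begin{bmatrix} -(R_{1f}+k_{fm}) & k_{mf}\\ k_{fm} & -(R_{1m}+k_{mf})\end{bmatrix}$$

to each voxel yields the **macromolecular pool size ratio**
(PSR = M₀ₘ/M₀f, related to myelin content), the free-pool relaxation rate
**R₁f**, the inversion efficiency **S_f** and the equilibrium signal
**M₀f**, with the exchange rate k_mf fixed (12.5 s⁻¹ in brain, 35.0 s⁻¹ in
BSA phantoms) or optionally estimated from ≥ 5 points. Intended users:
quantitative MRI researchers processing SIR acquisitions (NIfTI-1 or MAT v5
input) and anyone validating SIR estimators against a digital phantom.

The package provides:

- the closed-form forward model (`sir_signal()`, analytic 2×2 matrix
  exponentials),
- bounded Levenberg–Marquardt fitting per voxel (`fit_sir()`,
  `fit_sir_voxel()`), with broom-style `tidy()`/`glance()` and ggplot2
  `autoplot()` methods,
- a Rician-noise digital phantom for validation (`sir_phantom()`,
  `simulate_sir_series()`, `add_rician_noise()`),
- an evaluation layer: Lin's concordance correlation coefficient (`lccc()`),
  relative RMSE (`rmse_percent()`), percent-difference histograms, and the
  PSR → macromolecular-fraction conversion `f = PSR/(1+PSR)`,
- NIfTI-1 and MAT v5 I/O plus command-line entry points
  (`inst/cli/sir-fit.R`, `inst/cli/sir-simulate.R`).

## Worked example

Forward-simulate the white-matter validation phantom, fit it, and score the
maps against truth:

```r
library(sirqmt)

scheme <- sir_default_scheme()     # tI 15/15/278/1007 ms, tD 648/4171/2730/10 ms
sir_signal(scheme, sir_params(psr = 0.15, r1f = 1.0))
#> # A tibble: 4 × 3
#>      ti    td signal
#>   <dbl> <dbl>  <dbl>
#> 1 0.015 0.648  0.433
#> 2 0.015 4.17   0.910
#> 3 0.278 2.73   0.299
#> 4 1.01  0.01   0.632

phantom <- sir_phantom()           # 128x128: PSR 0.05-0.25, R1f 0.5-1.5 s^-1
noisy <- simulate_sir_series(phantom) |>
  add_rician_noise(snr = 250, seed = 20220329)
fit <- fit_sir(noisy, sir_fit_config(kmf = 12.5))
fit
#> SIR fit: 128x128x1 grid, 16384 voxels fitted (16384 converged) in 27.0 s
#>   free parameters: psr, r1f, sf, m0f
#>   fixed kmf = 12.5 s^-1

evaluate_sir_fit(fit, phantom)
#> # A tibble: 2 × 6
#>   parameter  lccc pearson_r rmse_pct     n n_excluded
#>   <chr>     <dbl>     <dbl>    <dbl> <int>      <int>
#> 1 psr       0.991     0.991     6.57 16384          0
#> 2 r1f       0.998     0.998     1.78 16384          0
```

Read: over 16,384 voxels at SNR 250, fitted PSR and R₁f agree with the
generating truth with Lin's concordance ≥ 0.99, and the per-voxel error is
6.6% (PSR) and 1.8% (R₁f) relative RMSE. `autoplot(fit)` shows the maps;
`tidy(fit)` gives one row per voxel.

From the shell, the same pipeline is:

```sh
Rscript inst/cli/sir-simulate.R --out simdir
Rscript inst/cli/sir-fit.R --input simdir/sim_noisy.nii.gz \
  --ti "15 15 278 1007" --td "648 4171 2730 10" --kmf 12.5 --out maps
```

which writes one NIfTI map per parameter plus a JSON provenance sidecar.

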