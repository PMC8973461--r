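---
title: "Methods: the two-pool SIR model, voxelwise fitting, and phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-pool SIR model, voxelwise fitting, and phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirqmt)
```

## The signal model

Selective inversion recovery (SIR) is a quantitative magnetization transfer
technique built on sequences available on any clinical scanner: a low-power,
on-resonance inversion pulse inverts the longitudinal magnetization of free
water protons ($M_{zf}$) while only partially saturating protons bound in
macromolecules such as myelin ($M_{zm}$). Exchange between the two pools
during recovery makes the free-pool signal biexponential in the inversion
time, and the amplitude of the fast-exchanging component carries the
myelin-sensitive quantity of interest: the macromolecular pool size ratio
$PSR = M_{0m}/M_{0f}$.

The package implements the coupled two-pool recovery after an inversion with
a *reduced* pre-delay $t_D$ (the time from the end of one readout to the next
inversion). Instead of waiting for full recovery ($t_D = 5\,T_1$), the
readout train is assumed to saturate both pools, so magnetization at the end
of the pre-delay is whatever regrows from zero in time $t_D$. Stacking
$\mathbf{M}_z = (M_{zf}, M_{zm})^T$:

$$
\mathbf{M}_z(t_I, t_D)
  = \left[e^{A t_I}\, S\,(I - e^{A t_D}) + (I - e^{A t_I})\right]\mathbf{M}_0,
\qquad
A = \begin{bmatrix} -(R_{1f}+k_{fm}) & k_{mf}\\ k_{fm} & -(R_{1m}+k_{mf})\end{bmatrix},
$$

with $S = \mathrm{diag}(S_f, S_m)$ the per-pool inversion efficiencies,
$\mathbf{M}_0 = (M_{0f}, PSR \cdot M_{0f})^T$, and detailed balance fixing
$k_{fm} = PSR \cdot k_{mf}$. The observed signal is proportional to the
$M_{zf}$ component (`sir_signal()`).

Seven parameters enter the model; three are fixed by standard assumptions so
that four points suffice for a voxelwise fit:

| parameter | meaning | default handling |
|---|---|---|
| $PSR$ | macromolecular pool size ratio (dimensionless) | free |
| $R_{1f}$ | free-pool spin-lattice rate (s$^{-1}$) | free |
| $S_f$ | free-pool inversion efficiency | free (absorbs B1 inhomogeneity) |
| $M_{0f}$ | free-pool equilibrium signal (a.u.) | free |
| $k_{mf}$ | macromolecular-to-free exchange rate (s$^{-1}$) | fixed: 12.5 (brain), 35.0 (BSA phantoms); optionally free with $\ge 5$ points |
| $S_m$ | macromolecular inversion efficiency | fixed at 0.83 (1-ms hard pulse estimate); override exposed |
| $R_{1m}$ | macromolecular spin-lattice rate (s$^{-1}$) | tied to $R_{1f}$ |

Two interpretation choices deserve emphasis because the underlying
literature leaves them open:

* **Magnitude convention.** Inputs are magnitude images with Rician noise,
  so by default the fit compares $|M_{zf}|$ to the data; a signed option
  (`magnitude = FALSE`) exists for phase-sensitive reconstructions. At the
  short-$t_I$ points the model value is strongly negative
  ($|M_{zf}| \approx 0.4\,M_{0f}$), far from the rectification floor at
  SNR 250, so the choice is benign there but is still surfaced as an option.
* **$R_{1m}$ tie.** "$R_{1m} = R_{1f}$" is treated as a live constraint,
  re-evaluated at every optimizer iterate, not an initialization frozen at
  the starting guess.

## Numerical evaluation

Each model evaluation needs $e^{A t_I}$ and $e^{A t_D}$. Because
$\mathrm{offdiag}(A) = (k_{mf}, k_{fm})$ with $k_{fm} k_{mf} \ge 0$, the
discriminant $(A_{11}-A_{22})^2 + 4 k_{fm} k_{mf}$ is non-negative: the
eigenvalues are always real, and the matrix exponential has the closed form
$e^{At} = c_1(t) A + c_0(t) I$ from the 2×2 eigendecomposition. Per-voxel
speed is the point of the toolkit, so this closed form is used everywhere;
when the eigen-gap falls below $10^{-9}$ the exact repeated-eigenvalue limit
$e^{At} = e^{\lambda t}(I + t(A - \lambda I))$ takes over. The test suite
pins this path against a general scaling-and-squaring exponential to
$10^{-10}$ over a 1,000-point random parameter sweep.

Times are seconds internally. Constructors and the command line accept
milliseconds by default (`units = "ms"`), matching how protocols are quoted,
and convert once at the boundary.

## Fitting

`fit_sir()` performs an independent bounded Levenberg–Marquardt fit per
voxel (`minpack.lm::nls.lm`, whose MINPACK core uses forward-difference
Jacobians). Model dispatch follows the presence of `kmf`: fixed `kmf` gives
the four-parameter residual; `kmf = NULL` gives the five-parameter one and
requires at least five scheme points (`dispatch_sir_model()`).

Choices the model itself does not dictate, fixed once here:

* **Initial guess**: $PSR = 0.10$, $R_{1f} = 1.0$ s$^{-1}$, $S_f = -0.95$,
  $M_{0f} = 1.2 \times \max|y|$ — mid-range of the biological box, with the
  signal amplitude scaled from the data.
* **Bounds**: $PSR \in [0, 1]$, $R_{1f} \in [0.05, 10]$ s$^{-1}$,
  $S_f \in [-1.05, 1.05]$, $M_{0f} \in (0, 10 \max|y|]$,
  $k_{mf} \in [0, 100]$ s$^{-1}$. $S_f$ extends slightly beyond the physical
  $\pm 1$ so that noise does not pin estimates to the boundary.
* **Tolerances**: cost and step tolerances of $10^{-10}$, at most 500
  iterations — tight enough that optimizer tolerance is never the accuracy
  bottleneck at SNR 250.
* **No multi-start, no retries**: non-convergent voxels are flagged in the
  `converged` map and excluded from evaluation, preserving single-fit
  throughput. A dense grid-search test confirms the single basin over the
  simulation box, which is why one start suffices there.
* **Degenerate voxels**: all-zero (or non-finite) signals are skipped with
  `converged = FALSE` and fill value 0 — background voxels outside a brain
  mask should cost nothing and contaminate nothing.

Voxels are strictly independent, so results are bit-identical for any
`threads` setting or visitation order; the suite asserts this.

## The digital phantom

`sir_phantom()` + `simulate_sir_series()` + `add_rician_noise()` regenerate
the validation study: a 128×128 grid with $PSR$ varying linearly 0.05–0.25
along columns and $R_{1f}$ 0.5–1.5 s$^{-1}$ along rows (both endpoints
included; the axis convention is ours and is recorded in the output
sidecar), $S_f = -1$, $M_{0f} = 1$, the optimized four-point scheme
($t_I$ = 15, 15, 278, 1007 ms; $t_D$ = 648, 4171, 2730, 10 ms), and Rician
noise at SNR 250 relative to $M_{0f}$: each value $v$ becomes
$\sqrt{(v+g_1)^2 + g_2^2}$ with $g_i \sim N(0, \sigma^2)$,
$\sigma = M_{0f}/\mathrm{SNR}$ — the canonical two-channel construction for
magnitude MR data. The default seed is 20220329; every seed is logged in the
sidecar and overridable.

What the phantom does *not* emulate: spatial noise correlation from
accelerated reconstruction, $B_0$/$B_1$ field structure, partial-volume
mixing, motion, and any deviation of real tissue from the two-pool model
(e.g. slower true $R_{1m}$). Passing the phantom validation therefore
demonstrates estimator correctness under the model's own assumptions, not
robustness to acquisition artifacts.

## Evaluation layer

Agreement between fitted and true maps uses Lin's concordance correlation
coefficient with population ($1/n$) moments,
$\rho_c = 2\,\mathrm{cov}(x,y) / (\sigma_x^2 + \sigma_y^2 + (\mu_x-\mu_y)^2)$,
decomposed into Pearson precision × bias-correction accuracy (`lccc()`).
Error magnitude is summarized as *relative* RMSE in percent,
$100\sqrt{\mathrm{mean}(((\hat\theta - \theta)/\theta)^2)}$
(`rmse_percent()`): a single "%" error figure per parameter is only
meaningful across quantities with different native units (s$^{-1}$,
dimensionless ratios) under a truth-relative reading, so that reading is
adopted deliberately and documented here because "RMSE in %" is not a
standard-named quantity. Evaluation is restricted to converged,
mask-true voxels and the exclusion count is reported
(`evaluate_sir_fit()`). `psr_to_fraction()` converts $PSR$ to the
macromolecular fraction $f = PSR/(1+PSR)$ used when regressing against
phantom concentration.

## Reproduced quantities and problem sizes

`scripts/acceptance.R` regenerates the full 128×128 phantom (16,384 voxels)
for a five-seed batch and reports LCCC and relative RMSE for $PSR$ and
$R_{1f}$; a single full-grid fit runs in well under a minute on one CPU.
The test suite exercises the same pipeline plus: exact recovery of all four
parameters to $10^{-6}$ relative on a noise-free 10×10 grid; the matrix
exponential sweep; an LM-versus-dense-grid cost bound on noisy voxels
(50×50×21×21 grid over the bounded box); the $PSR = 0$ scalar
inversion-recovery limit to $10^{-12}$; and the evaluation-layer identities.

Two published claims are intentionally out of reach of a simulation-only
validation and are not asserted anywhere: the BSA phantom parameter values
and the $f$-versus-concentration regression (requires scanner data), and
all cross-language timing comparisons (hardware-bound). They are noted here
so the package's scope is explicit.

## Known limitations

* MAT support is v5 only (real numeric arrays, compressed or not); v7.3
  (HDF5-based) containers and big-endian files are rejected with a clear
  error. DICOM/PARREC conversion is upstream of this toolkit.
* No spatial regularization or uncertainty maps; each voxel is fit alone.
* $S_m$ is a fixed point estimate; its published ±0.07 uncertainty is not
  propagated into the parameter maps.
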