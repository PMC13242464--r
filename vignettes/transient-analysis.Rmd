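---
title: "Analysing dark-to-high-light transients: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing dark-to-high-light transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phototransient)
```

## The measurement and the analysis problem

When a dark-adapted leaf is suddenly exposed to strong light
(~1000 µmol m⁻² s⁻¹), three things happen on the scale of seconds to
minutes: chlorophyll *a* fluorescence declines biphasically as quenching
mechanisms engage, the leaf's absorbance in the 450–650 nm green region
changes subtly as carotenoids are interconverted, and the xanthophyll pools
themselves — the β-branch VAZ cycle (violaxanthin → antheraxanthin →
zeaxanthin) and the α-branch LxL cycle (lutein epoxide ⇌ lutein) — shift
within the first seconds. phototransient implements the quantitative
analysis of such transients: spectroscopic quenching metrics, a constrained
Gaussian decomposition of the Δ-absorbance spectra, non-parametric kinetic
estimators, and replicate-level pool statistics for HPLC pigment time
series.

## Fluorescence metrics

The total emission from both leaf sides, $F_{tot}(\lambda, t) =
F_{up} + F_{dw}$, is converted to a photon flux and spectrally integrated:

$$J_F = \int_{655}^{850} 3.14\times10^{-3}\,
\frac{10^6}{N_a}\,\frac{10^{-9}\lambda}{hc}\,F_{tot}(\lambda)\,d\lambda
\quad [\mu\mathrm{mol\,m^{-2}\,s^{-1}}]$$

with $N_a = 6.02\times10^{23}$ mol⁻¹, $h = 6.62\times10^{-34}$ J s and
$c = 299\,792\,458$ m s⁻¹. The $3.14\times10^{-3}$ prefactor is applied
literally; its physical reading (π sr for Lambertian hemispherical
integration times a $10^{-3}$ scaling) is documented but not re-derived.
Two normalizations of the declining flux are derived from $J_F$:

* **F quenching** $(J_F(t_0) - J_F(t_i))/J_F(t_i)$ — algebraically the
  conventional NPQ form $(F_m - F_m')/F_m'$ with the first acquired sample
  standing in for the dark maximum. No saturating-pulse semantics are
  implied: $t_0$ is the first measurement, not an extrapolated $F_o$ or a
  flash-induced $F_m$.
* **Normalized decay** $1 - (J_F(t_0) - J_F(t_i))/(J_F(t_0) -
  J_F(t_{end}))$, anchored at 1 (start) and 0 (end) by construction.

The F690/F740 peak ratio is the maximum of the raw (never smoothed)
spectrum over 650–700 nm divided by the maximum over 700–800 nm, closed
intervals with 700 nm in both windows.

**Quadrature.** The integral is evaluated by the trapezoidal rule on the
native wavelength grid. The defining expression is a plain Riemann
integral with no rule named; trapezoid was chosen as second-order accurate
and robust to non-uniform grids. Halving the grid spacing of a smooth
spectrum changes $J_F$ by well under 0.1 % (asserted in the tests).

**Window bounds.** The integration bounds 655–850 nm are taken as
normative for $J_F$; the package does not attempt to reconcile them with
the 650–800 nm span a cut-off filter passes, and simply warns when the
supplied grid does not cover the window.

## Δ-absorbance and the constrained three-Gaussian model

Absorbance is computed from energy conservation, $A = 1 - T - R$, and the
transient signal is the difference from the dark spectrum,
$\Delta A(\lambda, t) = A(\lambda, t) - A(\lambda, t_0)$. Within
450–650 nm, each Δ-absorbance spectrum is modelled as three Gaussians:

| component | mean (nm) | sd (nm) | interpretation |
|---|---|---|---|
| G1 | 520 ± 2 | 8.5 (fixed) | electrochromic-shift-like feature |
| G2 | 535 ± 2 | 12.5 (fixed) | zeaxanthin/antheraxanthin-related, dominant late |
| G3 | 560 ± 2 | 5.0 (fixed) | narrow transient feature |

Standard deviations are fixed, means may move at most ±2 nm from nominal,
and amplitudes are free in sign (negative amplitudes capture bleaching of
converted pigments early in the transient). **No baseline/offset term is
included**: broader overlapping spectral broadening is deliberately left
unfitted, which produces a visible baseline discrepancy in the early
seconds — that mismatch is part of the model definition here, not a defect
to be corrected, and it is what the NRMSE reports.

**Optimizer.** Because the amplitudes enter linearly, the fit uses variable
projection: at any candidate mean vector the three amplitudes are solved by
linear least squares, and only the three box-bounded means are optimized
(L-BFGS-B). The 3-mean landscape is mildly multimodal, so the search is
multi-started from the nominal means plus every combination of
{−2, 0, +2} nm offsets (27 starts), then polished coordinate-wise with
golden-section search until the means move by less than 10⁻⁷ nm. Parameter
recovery on noiseless three-component spectra is well inside 10⁻⁴
(amplitudes) and 10⁻² nm (means); with additive noise at 10 % of the signal
maximum the dominant amplitude is recovered with < 10 % bias (both
asserted in the tests, 100 and 40 random spectra respectively).
Non-convergence of every start is flagged (`converged = FALSE`,
`nrmse = Inf`) rather than thrown, so a long fitting series never aborts on
one bad spectrum. When fitting a whole transient, each time point is fitted
independently (no temporal regularization); the previous time point's means
only seed an extra warm start.

**Relative weights.** The per-time normalization $w_k = |a_k| / \sum_j
|a_j|$ uses absolute amplitudes, because amplitudes are signed while the
reported weights are positive and sum to 1. This is an interpretive choice
(per-time, absolute-value normalization); a signed or per-trajectory
normalization would be defensible but was not adopted. When all three
amplitudes are zero — e.g. at $t_0$, where $\Delta A \equiv 0$ — the
weights are undefined and returned as `NA`, and downstream kinetic
estimators skip missing samples.

**NRMSE.** RMSE divided by the range (max − min) of the observed spectrum.
Range-normalization was adopted over mean- or sd-normalization; a constant
observed spectrum makes the statistic undefined and is an error.

**Smoothing.** A Savitzky–Golay filter (default window 15 points, order 3)
is available for display of noisy spectra only. Fitting always runs on raw
data.

## Kinetic estimators

All three estimators are deliberately model-free — no exponential or
biexponential fitting, since the quantities reported are half-times, not
rate constants:

* `halfTime()`: the midpoint between the first and **last sampled** values
  (not a fitted asymptote — transients end at 180 s and the estimator works
  on the finite record), and the earliest linearly interpolated crossing of
  that level. Undefined when the series never crosses. The estimator is
  invariant under affine transforms of the values, and on a sampled
  exponential with τ = 20 s at 0.35 s cadence it reproduces the closed form
  $20\ln(2/(1+e^{-9})) \approx 13.86$ s within 1 %.
* `timeToExtremeHalf()`: for non-monotone series (e.g. the G2 relative
  weight), the global extreme with the larger excursion from the first
  sample defines the target level halfway between start and extreme;
  the earliest crossing *on the way to the extreme* is returned.
* `firstExtremum()`: runs on the 2-period trailing moving-mean trendline
  (spreadsheet semantics: each point averaged with its predecessor, first
  point unchanged) and returns the earliest interior point strictly above
  (maximum) or below (minimum) both neighbours. A flat run qualifies
  through its first point when it is strictly above/below both flanking
  values; strict inequalities and the earliest-index tie-break keep the
  detection deterministic on noisy n = 3 replicate means. Half-times for
  fluorescence and Δ-absorbance are computed on raw series; only extremum
  detection uses the trendline, mirroring how the two kinds of quantity are
  usually presented.

## Pigment pool statistics

Concentrations are carried as mol (mol Chl a)⁻¹, which removes
between-leaf antenna-size differences. Two normalizations quantify the
dynamics over the 15-point sampling schedule
{0, 1, 2, 3, 5, 7, 10, 15, 20, 30, 40, 60, 90, 120, 180} s:

* **Dynamic pool** $(\max - \min)/\max \times 100\,\%$ per replicate, then
  mean ± SE across the n = 3 replicates. Computing per replicate first was
  chosen over pooling replicate means because the latter leaves no
  replicate spread to report an SE from. A pigment absent in darkness and
  formed under light (zeaxanthin in shade leaves, lutein epoxide in some
  species) scores exactly 100 %.
* **Normalized trend** $([Car]_{t_i} - [Car]_{t_0}) / (\max - \min)$,
  dimensionless, spanning exactly one unit over any non-constant series.

Missing determinations ("nd" below the detection limit) propagate as `NA`:
min/max are taken over non-missing samples, branch sums become missing at
any time point missing an addend, and statistical comparisons exclude
missing values pairwise. Nothing is imputed.

**De novo synthesis.** Whether a whole pool grew beyond interconversion is
tested at two levels — cycle pools (VAZ = Vio+Ant+Zea, LxL = Lx+Lut)
against their carotene precursors, and entire branches
(α = α-Car+Lut+Lx, β = β-Car+Vio+Ant+Zea+Neo). Each sampled time is
compared to the dark state with a two-sample, two-sided, equal-variance
Student's t-test across replicates (the classic Student form, per the
test's name; Welch would be defensible but was not adopted). Shapiro–Wilk
and Levene p-values are computed and reported as flags but do not gate the
t-test, and no multiple-testing correction is applied across the 15 time
points — both choices reproduce the per-time star convention
(\* p < 0.05, \*\* p < 0.01, \*\*\* p < 0.001) this kind of analysis
conventionally reports, and users needing family-wise control can apply
`p.adjust` to the returned p-value column.

**Correlation with quenching.** The destructively sampled pigment series is
the sparse anchor: the dense quenching record is linearly interpolated onto
the pigment sampling times inside its span (never the reverse — no pigment
values are invented between samples), and Pearson's r with its two-sided
t-distribution p-value (n − 2 df) is computed on replicate-mean pigment
trajectories.

## What the synthetic generator emulates — and what it does not

The generator exists so every pipeline stage is testable without
instrument data. Its defaults are the package's reference study
conditions, fixed once:

* spectral cadence 0.35 s over [0, 180] s (the upper end of realistic
  integration times); pigment schedule as above; n = 3 replicates;
* fluorescence: two-Gaussian emission (690/740 nm) scaled by the biphasic
  course $0.35 + 0.40\,e^{-t/8} + 0.25\,e^{-t/60}$ — a fast phase well
  inside the first 20 s, a slow phase stabilizing around 100–120 s, and a
  non-zero floor, split 50/50 between leaf sides;
* Δ-absorbance: G2 rising as $a_2^{max}(1 - 2^{-t/25})$ (half its plateau
  at exactly 25 s, the configurable recovery target), G1/G3 as transient
  rise-then-decay courses with one of them negative; reflectance and
  transmittance partition the non-absorbed light 50/50, an arbitrary but
  exactly invertible choice so energy conservation recovers A to machine
  precision in the noiseless case;
* pigments: linear first-order interconversion (Neo→Vio, Vio→Ant→Zea with
  slow reverse epoxidation, β-Car→Vio, α-Car→Lx, Lx⇌Lut) integrated with
  fixed-step RK4 at dt = 0.05 s, dark pools at realistic mol (mol Chl a)⁻¹
  magnitudes with zeaxanthin absent in darkness, lognormal replicate noise
  (σ = 0.08 on the log scale) keeping pools non-negative, and optional
  constant de novo influx into either branch.

Limitations worth keeping in mind when interpreting green tests:

* Linear first-order kinetics have real eigenvalues and therefore cannot
  oscillate; the generator reproduces net interconversion trends, not the
  early chaotic oscillations and mirror trends real leaves show. The
  mirror-trend diagnostic is exercised on constructed anti-correlated
  series instead.
* Spectral noise is additive white Gaussian ("electronic noise" with no
  structured spectral features); real instruments also drift.
* There is no mechanistic antenna model, no PSI/PSII photochemistry and no
  radiative transfer; a passing end-to-end test shows the *estimators*
  recover the *generating* kinetics, not that the generator is a leaf.

With zero influx each branch total is conserved along the exact trajectory
(to < 10⁻⁸; RK4 preserves the linear invariant to rounding). A de novo
influx sized so the branch-sum increase at 180 s equals 3× the replicate
noise on the dark branch pool is detected as a significant increase in
≥ 80 % of seeded repetitions; because the branch sum pools several
independently-noised pigments, its replicate SD is smaller than the
per-pigment noise and the n = 3 t-test has the required power.

## Numerical choices and degenerate inputs

* Wavelength windows are closed intervals everywhere; nearest-wavelength
  tracking breaks ties toward the lower wavelength.
* Non-positive $J_F$ makes F quenching undefined and is an error naming
  the offending time point; an identical first and last flux makes the
  normalized decay denominator degenerate (error).
* `fitGaussians` on an all-zero spectrum returns exactly zero amplitudes
  (the linear solve is exact) with undefined weights.
* Amplitudes below 10⁻¹⁴ are snapped to zero so that weight vectors are
  exactly 0/1 in the single-component case.
* CSV round trips write 15 significant digits and preserve values to at
  least 12.

## Problem sizes in the shipped tests

The test-suite and acceptance checks run at the following sizes, chosen to
exercise every guarantee at full fidelity while keeping a complete run in
the order of a minute: 100 random spectra for noiseless Gaussian recovery,
40 for the noisy-bias bound, 1000 random series for the brute-force oracle
equivalence of the pool statistics, 50 seeded repetitions for the de novo
detection rate, and Gaussian series fits at 2 s cadence (91 fits) for the
end-to-end recovery; the per-time fits are independent, so cadence trades
run time against temporal resolution and nothing else.
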