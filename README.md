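# phototransient

Analysis of **dark-to-high-light transients** in leaves at second-scale
temporal resolution. When a dark-adapted leaf is suddenly exposed to
saturating light (~1000 µmol m⁻² s⁻¹), chlorophyll *a* fluorescence
declines biphasically, the 450–650 nm absorbance develops subtle features
as carotenoids interconvert, and the xanthophyll-cycle pools — the β-branch
VAZ cycle (violaxanthin → antheraxanthin → zeaxanthin) and the α-branch
LxL cycle (lutein epoxide ⇌ lutein) — reorganize within seconds. This
package turns raw spectral time series and HPLC pigment tables into the
quantitative summaries of that response, for plant physiologists and
remote-sensing spectroscopists working on non-photochemical quenching
(NPQ) and rapid photoprotection.

## What it computes

**Fluorescence metrics** from up/downwelling leaf radiance
(W m⁻² sr⁻¹ nm⁻¹):

$$J_F = \int_{655}^{850} 3.14\times10^{-3}\,\frac{10^6}{N_a}\,
\frac{10^{-9}\lambda}{h c}\,F_{tot}(\lambda)\,d\lambda
\quad[\mu\text{mol m}^{-2}\text{ s}^{-1}]$$

plus the NPQ-equivalent *F quenching* $(J_F(t_0)-J_F(t_i))/J_F(t_i)$, the
normalized decay $1-(J_F(t_0)-J_F(t_i))/(J_F(t_0)-J_F(t_{end}))$, and the
F690/F740 peak ratio (red 650–700 nm vs far-red 700–800 nm window maxima).

**Δ-absorbance decomposition**: absorbance from energy conservation
$A = 1 - T - R$, the change against the dark spectrum
$\Delta A(\lambda,t)$, and a constrained least-squares fit of three
Gaussians — G1 (520 nm, sd 8.5), G2 (535 nm, sd 12.5), G3 (560 nm, sd 5) —
with fixed widths, means bounded to ±2 nm, signed free amplitudes and no
baseline term; per-time relative weights $w_k = |a_k|/\sum|a_j|$, NRMSE,
the 500–600 nm integrated Δ-absorbance and tracked 520/535/560 nm series.

**Kinetics**: model-free half-times (midpoint of first/last sample,
earliest interpolated crossing), half-time to a series' extreme, 2-period
moving-mean trendlines and first-relative-extremum detection.

**Pigment pools** (mol (mol Chl a)⁻¹, n = 3 replicates): the dynamic pool
percentage $(\max-\min)/\max\times100$ per replicate with mean ± SE,
normalized trends relative to the dark state, α/β-branch and VAZ/LxL cycle
sums, de novo synthesis tests (Student's t vs darkness with
Shapiro–Wilk/Levene flags and star coding), mirror-trend diagnostics, and
Pearson correlation of quenching with pigment trajectories on the sparse
sampling time axis.

**Synthetic data**: a fully seeded generator producing radiance,
reflectance/transmittance and replicate pigment kinetics with the
statistical structure the analysis assumes, so the entire pipeline is
testable without instrument data.

## Worked example

```r
library(phototransient)

cfg <- transientConfig(seed = 1)       # reference study conditions
sim <- simulateTransient(cfg)

fm <- fluorescenceMetrics(sim$fUp, sim$fDw)
fm[c(1, 30, 172, 515), ]
#>     time_s    j_f f_quenching normalized_decay peak_ratio
#> 1     0.00 0.0262      0.0000           1.0000     1.3438
#> 30   10.15 0.0177      0.4824           0.4879     1.3279
#> 172  59.85 0.0116      1.2622           0.1219     1.2822
#> 515 179.90 0.0096      1.7425           0.0000     1.2506

halfTime(fm$time_s, fm$j_f)
#> half-time: 9.87 s (from 0.02625 to 0.009631, linear crossing)
```

The flux falls to its record midpoint after 9.9 s (the generator's biphasic
parameters imply 9.72 s), quenching reaches 1.74 by 180 s, and the
F690/F740 ratio declines as re-absorption conditions change. Fitting the
Δ-absorbance spectrum at 180 s:

```r
dA <- deltaAbsorbance(absorbanceFromRT(sim$reflectance, sim$transmittance))
fitGaussians(wavelengths(dA), as.matrix(dA)[, ncol(as.matrix(dA))])
#>     mean_nm sd_nm     amplitude     weight
#> G1 520.2715   8.5  0.0001386099 0.01709934
#> G2 536.2582  12.5  0.0077689932 0.95840646
#> G3 562.0000   5.0 -0.0001985538 0.02449420
#> NRMSE: 0.08182, converged: TRUE
```

By the end of the transient the 535 nm component dominates (weight 0.96),
as expected when zeaxanthin/antheraxanthin-related absorbance takes over.
The pool statistics recover the dark-absent zeaxanthin pool as fully
dynamic, and its accumulation correlates tightly with F quenching:

```r
dynamicPoolSummary(sim$pigments)[, 3:6]
#>    pigment mean_percent se_percent n
#>      ...
#>      Vio         82.1        1.4   3
#>      Zea        100.0        0.0   3

fq <- fm$f_quenching
correlateQuenchingPigment(fm$time_s, fq, sim$pigments, "Zea")
#>   label         r      p_value n_points
#> 1   Zea 0.9225422 2.634403e-06       14
```

`runAll(cfg, outDir)` chains every stage and writes the derived CSV tables,
a summary JSON and a checksum manifest; `inst/scripts/phototransient.R`
exposes the same stages as shell subcommands
(`simulate`, `fluor`, `abs`, `pigments`, `correlate`, `run-all`).

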