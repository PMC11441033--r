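# aortaflow

Quantification of ascending aortic haemodynamics from time-resolved 3D
velocity fields of the kind produced by 4D flow cardiac MR, with the
case–control and biomarker-correlation statistics that typically follow.

Dilation of the ascending aorta reshapes blood flow: outflow jets become
eccentric, wall shear stress (WSS) drops, and its direction oscillates over
the cycle. Studies linking these haemodynamic markers to circulating
biomarkers of inflammation and matrix remodelling (IL-6, COL1α1, MMPs,
TIMPs) need a reproducible pipeline from raw velocity lattices to a
correlation table with false-discovery control. `aortaflow` implements that
pipeline for researchers working with 4D flow data — and, because patient
data cannot ship with code, it also implements the synthetic substrates
(flow phantoms with closed-form WSS, cohort tables with planted effects)
that make every stage testable.

## The markers

Given a velocity field $\vec u(\vec x, t)$, a binary lumen mask, and two
landmarks (aortic valve, brachiocephalic trunk) delimiting the ascending
aorta:

- **WSS**: $\vec\tau = \mu\,\partial\vec u_t/\partial n$ at the wall,
  estimated by sampling velocity at 3 points along the inward normal,
  enforcing no-slip, and fitting $a\,d + b\,d^2$ through the origin per
  tangential component ($\mu = 3.2$ mPa·s by default).
- **Peak WSS**: $\lVert\vec\tau\rVert$ at the frame of maximum forward flow
  through the most proximal of seven equidistant analysis planes.
- **TAWSS**: $\frac1T\int_0^T \lVert\vec\tau\rVert\,dt$.
- **OSI**: $\frac12\left(1 - \lVert\int_0^T\vec\tau\,dt\rVert\big/
  \int_0^T\lVert\vec\tau\rVert\,dt\right) \in [0, 0.5]$.
- **Flow displacement**: $\lVert C_\text{flow} - C_\text{lumen}\rVert /
  D_\text{eff}$ per analysis plane, forward-flow-weighted, with
  $D_\text{eff} = 2\sqrt{A/\pi}$.
- **Axial/circumferential WSS**: projections of $\vec\tau$ onto the
  centerline tangent (projected into the wall plane) and its cross product
  with the wall normal.

Regional summaries report the mean and the 99th percentile over wall
samples (plain maximum over the seven planes for flow displacement). The
statistics layer applies a Lilliefors normality gate at α = 0.05 to choose
Student t / Pearson vs Mann–Whitney / Spearman, Fisher's exact test for
categorical variables, and Benjamini–Hochberg control at FDR < 0.05 over
the full biomarker × haemodynamics × stratum correlation family.

## Worked example

```r
library(aortaflow)

# A pulsatile Poiseuille phantom: R = 10 mm, 1 mm voxels, 20 frames,
# waveform peaking at frame 6; analytic peak wall WSS = 2*mu*vmax/R = 0.64 Pa
spec <- flow_phantom_spec(tube_radius = 10, tube_length = 40,
                          voxel_spacing = 1, n_frames = 20,
                          profile_kind = "pulsatile_parabolic",
                          waveform_params = list(v_max = 1, peak_frame = 6))
phantom <- build_phantom(spec)
subject_summary(phantom$velocity, phantom$seg, phantom$landmarks,
                default_config())
#> <hemo_summary>  peak frame 6 | 2100 regional wall samples
#>   peak WSS  mean 0.542  max 1.200 Pa
#>   TAWSS     mean 0.271  max 0.600 Pa
#>   OSI       mean 0.0000 max 0.0000
#>   flow disp mean 0.0000 max 0.0000
#>   axial/circ mean WSS at peak: 0.542 / 0.000 Pa
```

The peak frame is recovered exactly; the mean peak WSS of 0.54 Pa sits 15%
below the analytic 0.64 Pa at this coarse 1 mm resolution (−4% at 0.5 mm,
−1% at 0.25 mm — the voxel-grade wall localization bias analyzed in the
vignette). TAWSS is half the peak value because the raised-cosine waveform
averages to one half; OSI and flow displacement vanish for this
unidirectional axisymmetric flow.

```r
# A synthetic 47-case / 50-control cohort with two planted correlations
tb <- generate_cohort_table(default_cohort_spec(seed = 1))
ex <- lloq_exclude(tb)          # drops MMP12, TIMP3 (censored in >50%)
ct <- build_correlation_table(ex$table)   # 9 x 8 x 3 = 216 cells
subset(ct, bh_rejected, select = c(x, y, stratum, method, r, p_adjusted))
#>         x         y stratum  method      r p_adjusted
#> 75    IL6 max_tawss   cases pearson  0.522     0.0315
#> 85 COL1A1   max_osi   cases pearson -0.505     0.0315
```

The two BH-surviving cells are exactly the planted pairs.

A thin command-line interface wraps the same functions
(`inst/cli/aortaflow`): subcommands `phantom`, `hemodynamics`, `cohort`,
`pipeline`; see `?cli_run`.

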