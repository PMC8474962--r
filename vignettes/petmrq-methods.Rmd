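---
title: "Models and methods in petmrq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in petmrq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmrq)
```

`petmrq` quantifies small-animal tumor imaging studies that pair MRI
(anatomy and diffusion) with static and dynamic FDG-PET, and validates
every analysis operation against digital phantoms whose ground truth is
known by construction. This vignette describes the models, the tunable
parameters, the numerical choices, and what the phantoms do and do not
establish about real data.

## Geometry and units

All volumes are axis-aligned 3D grids with strictly positive voxel
spacing in mm and a world origin; voxel `(1,1,1)` sits at the origin and
world coordinates are `origin + (index - 1) * spacing`. No rotation or
shear is modeled: the studies this package targets register nothing
formally, and masks move between the MRI and PET grids by
nearest-neighbour resampling through world coordinates
(`resample_mask_to()`). Making the reference grid explicit — rather than
trusting silently matching headers — is a deliberate guard against
cross-modality misalignment.

Units are mandatory metadata (`Bq_per_ml`, `kBq_per_ml`, `SUV`,
`signal_au`, `mm2_per_s`). Operations refuse unit-mismatched input
instead of guessing; a NIfTI file without its JSON sidecar reads back
with units flagged `unknown`. Negative header spacings (seen in some
vendor exports) are normalized to positive values with the flipped axes
recorded.

## Diffusion MRI

The DWI signal follows the mono-exponential model
$S_b = S_0 e^{-b \cdot \mathrm{ADC}}$. With the usual two b-values
(0 and 1000 s/mm²) the ADC is the closed form
$\ln(S_0/S_b)/b$; with more b-values a per-voxel least-squares slope of
$-\ln S_b$ on $b$ is used. Voxels with any nonpositive signal are
flagged invalid (`NA`) and excluded from all statistics rather than
clipped — the logarithm is undefined there and clipping would bias the
map. No spatial smoothing is applied before fitting: vendor ADC maps
come from unspecified proprietary pipelines, so the defensible default
is the raw voxelwise fit. Anatomic tumor volume is voxel count times
voxel volume, the 3D equivalent of summing per-slice segmented areas.

The DWI phantom uses the acquisition geometry of a typical preclinical
protocol (67 × 93 matrix, 0.3 × 0.3 mm in-plane, 1 mm slices), a tumor
ellipsoid whose smooth radial ADC field averages exactly the requested
mean (default 1.07 × 10⁻³ mm²/s, with a ±12 % core-to-rim gradient —
restricted core, freer rim), and Rician noise
$\sqrt{(S+\epsilon_1)^2+\epsilon_2^2}$, the correct model for magnitude
MR images. At SNR(b=0) = 20 the Rician floor biases the two-point ADC
by well under the 3 % budget the tests enforce; at very low SNR it
would not, which is a property of the estimator, not a defect of the
phantom.

## Static PET

SUV is concentration times body weight over injected dose (tissue
density 1 g/ml); doses assayed away from injection time decay-correct
with the F-18 half-life (109.77 min). Two segmentation rules are
implemented exactly as practitioners use them:

- **Isocontour** (`segment_iso40()`): threshold at 40 % of SUVmax
  within the search region (minus exclusion masks over bladder and
  kidneys), keeping the 26-connected component that contains the
  hottest voxel. The seeded component reproduces what an isocontour
  tool grown from the lesion does; an unseeded global threshold would
  also capture the excretory organs. Membership uses `>= threshold`
  (not strict `>`) so the maximum voxel survives even a degenerate
  uniform image. The threshold is reported internally at full precision
  and displayed rounded to one decimal, the convention used when such
  thresholds are quoted (0.4 × 3.8 = 1.52 reports as 1.5).
- **Fixed threshold** (`segment_fixed()`): all voxels at or above a set
  SUV (default 2.5), no connectivity filter — the rule is "all
  qualifying voxels", and an empty result is flagged, not an error,
  because murine tumors frequently fall below thresholds calibrated on
  human uptake. The mean liver SUV (`liver_reference()`) is reported
  per scan as the QC quantity that explains why: mouse liver background
  sits near 0.5 SUV, several-fold below the 2–3 SUV of human livers.

MTV is mask voxel count times voxel volume; TLG is defined — not
measured — as SUVmean × MTV, so the identity holds to machine precision
by construction and the tests assert exactly that. No partial-volume
correction is applied anywhere, matching common preclinical practice;
measured SUVmax on blurred phantoms is therefore expected to sit below
the simulated tissue maximum.

## Dynamic PET and kinetic modeling

The tracer model is the irreversible two-tissue-compartment system

$$\frac{dC_1}{dt} = K_1 C_p - (k_2 + k_3)\,C_1, \qquad
  \frac{dC_2}{dt} = k_3 C_1,$$

with total tissue signal $C_T = (1-v_b)(C_1+C_2) + v_b C_p$ and net
influx constant $K_i = K_1 k_3/(k_2+k_3)$. The simulated input function
is a tri-exponential Feng-type bolus
$C_p(t) = (A_1 t - A_2 - A_3)e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} +
A_3 e^{-\lambda_3 t}$ with $C_p(0)=0$; the defaults (peak ≈ 535 kBq/ml
near 22 s, 1-h tail ≈ 184 kBq/ml) are sized so that, with the default
kinetics ($K_1 = 0.24$, $k_2 = 0.36$, $k_3 = 0.07$ min⁻¹, giving
$K_i = 0.0391$), late-frame tumor SUV lands in the range observed in
FDG-avid xenografts. A parametric bolus is the standard simulation
choice when no measured arterial curve exists.

**Numerical solution.** The 2TC system is linear, so instead of a
generic adaptive stiff integrator the simulator uses an
exponential-trapezoidal update on a fine uniform grid (0.1 s): the
update for $C_1$ is exact when $C_p$ is piecewise-linear on the grid,
and $C_2$ follows by cumulative trapezoid. This is faster by orders of
magnitude than an adaptive solver called per scan — which matters for
the 100-seed recovery studies — and the test suite cross-checks it
against `deSolve::lsoda` at tight tolerances. Reported frame values are
averages of $C_T$ over each frame interval, not mid-time point samples:
with 2-s early frames the distinction is material.

**Frame scheme.** The default 1-h dynamic schedule is 5 × 2 s,
5 × 10 s, 2 × 120 s, 3 × 300 s, 4 × 600 s — 19 contiguous frames
totalling 3600 s, with mid-times used as the TAC time axis.

**Input function.** `derive_idif()` ranks voxels in a user-drawn
vena-cava box by summed concentration over the bolus window (mid-times
≤ 60 s) and averages the top *k* = 7 as a fixed set across all frames.
Ranking on the early window targets the bolus and avoids late tissue
spill-in; whether a fixed set or per-frame selection is the "right"
reading of a hottest-voxel rule is genuinely open, and the fixed set is
this package's documented choice (it keeps the late tail unbiased). A
QC flag records whether the curve has the expected single early peak,
standing in for the visual inspection a physicist would do.

**Patlak analysis.** For frames with mid-time ≥ t\*,
$y_i = C_T(t_i)/C_p(t_i)$ is regressed on
$x_i = \int_0^{t_i} C_p\,d\tau / C_p(t_i)$ (trapezoidal AUC anchored at
$(0,0)$ — frames start at injection, so the curve is assumed zero
before the first mid-time; with a constant synthetic input this anchor
shifts the intercept by $K_i t_1/2$, never the slope). The slope is
$K_i$, the intercept the effective distribution volume, and the
standard error of the slope gives the `rel_se_pct` quality gate: fits
at or above 10 % relative SE are flagged. t\* defaults to 20 min —
uptake in these tumors rises rapidly over the first ~20 min and then
increases slowly, and on noiseless simulated data moving t\* from 20 to
30 min changes $K_i$ by under 0.5 %, so the default is insensitive.
Plain OLS is used (no weighting): weighted variants depend on vendor
settings that are rarely reported.

Two deliberate modeling positions: the whole-blood IDIF is used as the
plasma input without metabolite, plasma/whole-blood, or partial-volume
correction (matching the uncorrected practice the workflow emulates);
and the default blood fraction in `two_tc_params()` is $v_b = 0$,
because the Patlak slope of an uncorrected tissue curve estimates
$(1-v_b)K_i$ — a ~5 % systematic shift at $v_b = 0.05$ that no fit can
remove. The noisy cohort generator *does* draw $v_b \sim U(0.03, 0.08)$
as realism, and the recovery tests budget for the resulting bias inside
their 10 % envelope.

$\mathrm{MR}_{FDG} = K_i \cdot \text{glucose}/\text{LC}$ with defaults
6.0 mmol/l (= 6.0 µmol/ml) and LC = 0.6, i.e. a factor of 10. The
result is reported in µmol·min⁻¹·ml⁻¹; quoted values of the same
quantity sometimes omit the per-volume denominator ("µmol/min"), which
is the same number under the 1 g/ml density convention used here.

## PET phantom noise

Noise is Poisson on expected counts
$N = C \cdot V \cdot \Delta t \cdot s$ (concentration × volume × frame
duration × sensitivity), back-converted to concentration. This
reproduces the dominant variance structure of reconstructed dynamic
PET: 2-s bolus frames are noisy, 600-s late frames are quiet, and small
ROIs (the 7-voxel input region) are noisier than the tumor. The
effective sensitivity default, 0.08 counts per Bq·s, approximates a
modern small-animal ring; it is a single calibration constant, not a
scanner model — reconstruction-induced noise correlations, randoms and
scatter are explicitly not simulated, so phantom recovery results bound
estimator behaviour under idealized counting noise only. Poisson means
above 10⁶ switch to the normal approximation to avoid integer overflow;
at those counts the approximation error is far below any tolerance in
use. The PSF is an axis-separable Gaussian (default FWHM 0.8 mm,
truncated at 4σ, edge-renormalized).

The 64³ × 0.4 mm default scene holds the tumor ellipsoid (with a
radial uptake heterogeneity field normalized to mean 1, so the
tumor-mean TAC stays exactly on the nominal kinetic curve while SUVmax
sits above SUVmean), a thin vena-cava cylinder carrying the input
function, two kidneys and a filling bladder with excretion-ramp
activity — the structures a fixed-threshold segmentation must exclude —
over a low body background. Structure overlap is a validation error,
and every generator is deterministic under its seed.

## Histology

Nuclei images are dark ellipses on a bright background: per-nucleus
axes are drawn first (±15 % around the 2.6 µm default radius) so the
placement rule can enforce a true pairwise separation —
$(r_i + r_j)(1-\text{overlap}) + \text{gap}$ — by rejection sampling;
densities whose exclusion discs would exceed ~45 % coverage are refused
up front (random sequential placement saturates near 55 %). Exactly
`round(density × area)` nuclei are placed, so the generator's truth
density is exact by construction.

Counting thresholds each ROI at the darkest-quartile intensity, capped
by an Otsu split — the percentile alone fails when nuclei cover less
than the percentile of the field, the Otsu cap alone would be fooled by
strongly non-bimodal fields; the minimum of the two is robust across
the densities of interest. A 3×3 opening removes specks, a
distance-transform watershed (tolerance 0.6) splits touching nuclei,
and components under 5 µm² are discarded. An ROI whose intensity spread
(1st–99th percentile) is below 0.2 is declared nucleus-free rather than
thresholded into noise. These detector parameters were tuned on the
package's own phantoms; absolute agreement with any particular
histology software on real slides is not claimed — only the density
statistic, which is what feeds the treatment comparison.

## Cohort simulation

`simulate_cohort()` emulates a longitudinal progression study plus a
treatment arm at the scale of the motivating study design: 18 mice with
weekly T2/PET imaging over weeks 3–5 under a thinning scan design
(14/10/8 T2 scans, 12/10/4 PET scans, two week-4 scans static-only —
giving 32 T2, 26 PET and 24 dynamic scans), and 9 treatment-study mice
(5 treated, 4 control) with endpoint DWI + histology at week 7/8 (9 DWI
rows). Weekly anatomic volumes follow per-mouse lognormal growth
calibrated so the week means target ≈ (177, 666, 936) mm³; MTV couples
linearly to volume, SUV moderately to $K_i$, ADC negatively to volume,
and $K_i$ is drawn within the range its downstream conversion keeps
$\mathrm{MR}_{FDG}$ inside the plausible 0.12–0.61 window. The
between-mouse CV (0.20) and growth CV (0.15) were set once so the
sampled weekly means stay within the ±15 % calibration band at these
small n; the n = 4 week-5 PET subsample is the least stable cell and
can wander outside it. Treatment shifts endpoint ADC up (×1.2), volume
down (×0.35) and density down (×0.77) — effect sizes consistent with a
responding chemotherapy arm and large enough that the exact
Mann–Whitney test at n = 5 vs 4 can reach significance (the smallest
attainable two-sided p at these sizes is 2/126 ≈ 0.016).

The cohort generator produces *tables* with per-scan truth; the
pipeline (`run_pipeline()`) then re-measures each scan through the
image path: voxelized masks for T2 volumetry, blurred static phantoms
for PET segmentation and metrics, simulated noisy TACs for Patlak, DWI
phantoms for ADC, nuclei images for density. Per-scan image sizes
(56³ static PET, 160×160×20 T2, 67×93×20 DWI, 0.09 mm² histology
fields) keep a full 67-scan demo run to a few seconds while remaining
at the voxel scale of the real protocols.

## Statistics

Group comparisons use an exact Mann–Whitney test: mid-rank U, two-sided
p defined as $P(|U - n_1 n_2/2| \ge |u_{obs} - n_1 n_2/2|)$ under full
enumeration of all $\binom{n_1+n_2}{n_1}$ assignments (ties handled by
mid-ranks inside the enumeration). At the 4–5 animals per arm typical
of these studies, asymptotic p-values are unreliable; enumeration is
cheap up to $n_1+n_2 = 20$ and the symmetric-tail definition is
deterministic and matches the standard exact test whenever the null
distribution is symmetric (always, without ties). Larger samples fall
back to the tie-corrected, continuity-corrected normal approximation.
Spearman correlations use exact permutation p for n ≤ 9 and the
t-approximation beyond; regression r² is reported as 1 − SS_res/SS_tot
with the convention r² = 0 for constant y. The normality screen wraps
the standard Shapiro–Wilk implementation and never changes which test
is run — group comparisons stay nonparametric regardless. No
multiple-testing correction is applied, matching the analysis style the
package reproduces; users comparing many markers should adjust
externally.

## What passing tests do and do not show

The phantoms establish that each estimator inverts its own generative
model: noiseless ADC recovery to 10⁻¹⁰, Patlak $K_i$ within 2 % of
$K_1k_3/(k_2+k_3)$ on noiseless curves, median $K_i$ error within 10 %
under count noise, nuclei counts within the stated bands. They do not
establish accuracy on real scanners: reconstruction noise correlations,
motion, dispersion and delay of the input function, partial-volume
effects, and stain variability are all outside the generative models,
and the corresponding corrections are deliberately out of scope. The
package's value on real data is that every formula, threshold, gate and
convention is explicit, versioned and tested.
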