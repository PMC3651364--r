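---
title: "Models and methods behind spiralPVM"
author: "spiralPVM maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spiralPVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralPVM)
```

# Scope

spiralPVM re-implements, as a tested pipeline, the analysis of
retrospectively gated spiral myocardial phase velocity mapping (PVM):
three-directional myocardial velocity quantification over the entire
cardiac cycle, including atrial systole. Because no in vivo scans ship
with the package, every stage is exercised against a synthetic
moving-annulus phantom with exact ground truth. This vignette explains
the models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic cohort does — and does not — establish
about real data.

# The acquisition model

`AcquisitionParams()` holds the sequence constants of the reference
protocol: velocity sensitivities (venc, the velocity producing a phase
shift of $\pi$) of 30 cm/s through-plane and 20 cm/s in-plane, 13 spiral
interleaves of 12 ms readout, 21 ms acquired temporal resolution, a
360 mm field of view on a 256 × 256 matrix (1.4 mm pixels, interpolable
to 0.7 mm by zero-filling), retrospective interpolation to 60 cardiac
phases, an 8 mm slice and a 5 mm navigator window. One interleave is
acquired per cardiac cycle and the reference plus three encoded datasets
follow a single dummy cycle, so a complete acquisition takes
$13 \times 4 + 1 = 53$ cycles at full respiratory efficiency.

Phase encoding is the standard linear phase-contrast mapping
$\varphi = \pi v / \mathrm{venc}$; the reference set carries only the
background phase, each encoded set adds the velocity term, and all four
sets receive independent Gaussian phase noise before wrapping to
$[-\pi, \pi)$. Velocities at or beyond venc are rejected by the encoder
(they would wrap), and the decoder performs no unwrapping — healthy
myocardial velocities sit far below both vencs, and near-venc values
raise a warning only.

# The motion model

The phantom's velocity field is separable,
$v(t, \theta, d) = f(t)\, m(\theta)\, g(d)$, per direction:

* **Global profiles** $f(t)$ are periodic trains of raised-cosine
  (Hann) bumps, one per named peak: systolic (S), early-diastolic (D)
  and atrial-systolic (AS) peaks in the longitudinal and radial
  directions, and the biphasic early-systolic pair C1/C2 plus the
  early-diastolic C3 circumferentially. Compact support was chosen over
  Gaussian bumps deliberately: the C1/C2 pair sit roughly 100 ms apart,
  and Gaussian tails wide enough to survive 21 ms sampling destroy the
  small C2 extremum, whereas Hann bumps have exactly zero interference
  beyond their half-width.
* **Peak prescriptions** default to the healthy-cohort means per slice
  level (basal, mid, apical): amplitudes in cm/s and peak times as
  percentages of systolic or diastolic length. The mid-level global
  circumferential profile has no C3; the apical C3 is positive, opposite
  to the basal one (ventricular untwisting). A small fixed end-systolic
  radial dip (−1 cm/s, 40 ms half-width) marks end systole — the first
  negative radial peak, present in every generated curve.
* **Half-widths** (ms) are model choices, constrained from below by the
  requirement that a 21 ms acquisition must not alias any peak (the
  worst-case sampling loss plus noise has to stay inside the 5%
  recovery margin) and from above by peak separation: S$_L$ solved (see
  below) within [90, 200], D$_L$ 110, AS$_L$ 105; S$_R$ solved within
  [100, 220], D$_R$ 85 (bounded by the end-systolic dip rebound), AS$_R$
  105; C1 95, C2 105, C3 100.
* **Periodicity.** A closed cycle demands $\oint f\,dt \approx 0$. The
  width of the dominant systolic bump per direction is solved so the
  longitudinal and radial integrals vanish, with the extra constraint
  that the solved bump must not wrap across the R-wave into the
  atrial-systolic support at short cycles. The circumferential profile
  is left at its defaults; its residual cycle mean (≈ −0.15 cm/s) is of
  the same order as the closure residuals reported for in vivo curves.
* **Exact prescriptions.** Bump coefficients are adjusted by a small
  fixed point so the realized extrema of the continuous profiles equal
  the prescribed amplitudes even where bumps overlap; the realized
  extremum times are recorded as ground truth.
* **Regional modulation** is a ±30% cosine in the angular coordinate,
  peaking in the lateral wall, so lateral-dominant diastolic velocities
  are reproduced qualitatively. The **transmural gradient** scales the
  radial component linearly from endocardium to epicardium
  ($1 + 0.45\,(0.5 - d)$), matching the observed endo > mid > epi
  ordering of radial peaks.
* **Cohort variability** draws a per-subject global amplitude scale
  (SD 0.15) times small per-peak jitters (SD 0.10), timing jitter shared
  per cardiac event (the systolic excursion, early filling and atrial
  contraction move the wall in all directions together) and scaled by
  each peak's cohort percentage SD, end systole N(349, 38²) ms and RR
  N(994, 121²) ms, all truncated. Event-shared timing keeps D$_L$ and
  D$_R$ synchronous, as early filling is one event. Minimum peak
  separations (C2 ≥ C1 + 115 ms; D$_R$ ≥ end systole + 110 ms) are
  enforced after jitter so every generated curve stays resolvable.

The rendered field is calibrated per frame so the mask-averaged velocity
equals $f(t)$ exactly — the prescribed amplitudes are global region
averages, which is also what the cohort tables report. Contours are
concentric 72-vertex circles (endocardium 20 mm, epicardium 30 mm at
end-diastole, about 7 acquired pixels of wall) whose radii follow the
integrated global radial velocity; pixels outside the annulus have zero
velocity.

# Reconstruction

`phaseDifferenceToVelocity()` applies
$v_c = \mathrm{venc}_c\,\mathrm{wrap}(\varphi_c - \varphi_\mathrm{ref})/\pi$
per pixel. `retroGateInterpolate()` interpolates linearly onto
$t_k = k\,RR/60$, closing the cycle across the R-wave (retrospective
gating implies a closed cycle). Background correction follows the
stationary-phantom route: the phantom's velocity maps are median-smoothed
and subtracted pixel by pixel. Two details matter:

* The phantom's background phase is static, so the pipeline
  time-averages the phantom maps before smoothing
  (`timeAverageSeries()`): frame averaging reduces the map noise by
  $\sqrt{\text{frames}}$ and, unlike spatial filtering alone, leaves no
  spatially correlated residue in regional averages. Per-frame median
  filtering was tried first and measurably degraded small-peak recovery
  — the 5 × 5 median leaves correlated noise that does not average out
  over a region, and its bias on a curved background offsets whole
  regional curves. After time averaging, a light 3 × 3 median removes
  residual outliers (the median's curvature bias scales with the window
  squared, so the smaller kernel is also the less biased one).
* No eddy-current physics is modelled; the background is an empirical
  second-order 2-D polynomial per phase set, which the phantom
  subtraction removes exactly in the noise-free limit.

# Spiral trajectory and gridding

The trajectory is an idealized constant-angular-density Archimedean
spiral with samples uniform in arc length; interleave $j$ is interleave
0 rotated by $2\pi j/13$, the turn count $M/(2 N_\mathrm{int})$ makes
the full interleave set exactly Nyquist-sampled at the stated FOV, and
$k_\mathrm{max} = M/(2\,\mathrm{FOV})$. No gradient or slew constraints
are modelled.

Gridding uses a Kaiser–Bessel kernel (width 4 cells on a 2× oversampled
grid, $\beta$ from the standard oversampling formula), analytic
deapodization and a central crop. Density compensation is a radially
binned inverse-density weight computed from the trajectory itself
(annulus area over sample count on rings of width $1/(4\,\mathrm{FOV})$,
clipped at $k_\mathrm{max}$ and capped against near-empty outer bins).
An analytic $|k|$ ramp — natural for constant-angular-velocity spirals —
is *wrong* for arc-length-uniform sampling, whose density is nearly
uniform except at the dense centre where the interleaves converge;
applying the ramp high-passes the image. The overall scale is calibrated
against the point-spread function with the band-limited point source as
reference. Reconstructions are assessed against the circularly
band-limited target: a sharp binary disc cannot be recovered below
NRMSE ≈ 0.10 from $|k| \le k_\mathrm{max}$ data by *any* method, so the
meaningful method error is measured relative to the band-limited disc
(the gridder achieves ≈ 0.036 on the 32 × 32 test).

The exact direct-DFT sampler is the forward oracle; its adjoint is used
for inner-product consistency testing. Zero-filled Fourier interpolation
splits the Nyquist row/column to stay real and reproduces the original
samples exactly.

# Geometry, segments and curves

Velocities are transformed into the LV cylindrical system: longitudinal
positive towards the apex, radial positive towards the per-frame mask
centre of mass, circumferential positive clockwise as viewed from the
apex. The angular coordinate runs from the anterior LV–RV junction
towards the lateral wall (half-open bins, the junction pixel belongs to
the anterior segment); the standard AHA orderings give 6 segments
of 60° for basal/mid slices, 4 of 90° apically, and 24 equal 15°
segments for the colour maps. Transmural depth is assigned by the
nearest of 360 equally spaced endocardium-to-epicardium rays, split at
thirds into endocardial, mid-wall and epicardial layers. Region averages
are unweighted pixel means; the centre of mass is computed from the
binary mask (not intensity-weighted) for noise robustness.

The pipeline applies *conservative contouring*: both borders are pulled
one pixel into the wall before rasterization. Without it, boundary
pixels mix with the zero-velocity exterior through the retro-gating
interpolation and dilute regional means by 2–3%; conservative manual
contouring is standard practice in vivo for the same reason.

# Peak detection and timing

End systole is the first negative radial minimum after the global
systolic maximum, detected on a 3-frame-smoothed curve and required to
dip at least 0.15 cm/s below zero (a guard against noise wiggles at the
systolic zero crossing). Diastasis onset is the first time after the
early-diastolic radial peak at which $|v_R|$ stays below 25% of
$|D_R|$ for two phases; the atrial onset is the last local minimum of
$|v_R|$ before the atrial radial peak. The "clearly defined sections"
of the cycle are not given quantitative definitions in the literature,
so the 25%/2-phase thresholds are package decisions and configurable.

Named peaks are window-restricted extrema (S in systole, D between end
systole and diastasis, AS after the atrial onset; C1 the first negative
circumferential extremum, C2 the next opposite-signed one — sign
unconstrained apically, where it varies with slice position — and C3
early-diastolic, with its window opened one phase before end systole
because the apical C3 peaks within a percent or two of it). Extremum
*selection* runs on a lightly smoothed copy of the curve; the amplitude
and time are then *refined* on the raw curve by a three-point
log-parabolic vertex fit (exact for Gaussian peaks, and recovering most
of the finite-sampling loss for smooth compact peaks) with a 1.2× gain
cap. A peak is absent when no extremum exceeds a noise floor of 3× the
diastasis-window variability, estimated from successive differences —
plain SDs would be inflated by the longitudinal early-diastolic
recovery, which outlasts the radially defined diastasis onset.

The pipeline quantifies peaks on the acquired-resolution region curves
(the corrected series before 60-phase interpolation, which it holds);
the 60-phase reconstruction is used for markers, normalization and the
cohort maps. Linear interpolation onto the 60-phase grid attenuates
narrow extrema by a few percent, and there is no reason to pay that
penalty where the acquired-resolution data exist.

Times to peak are reported from the R-wave (ms), as percentages of
systolic or diastolic length, and as fixed-length ms on the nominal
cycle (percent/100 × 350 ms systole, or 350 + percent/100 × 650 ms
diastole). For paired differences the diastolic offset cancels, giving
the affine rule of 3.5 (systolic) or 6.5 (diastolic) ms per percent.
Printed tables round half away from zero to one decimal. E/A is the
magnitude ratio of the early-diastolic to atrial-systolic peak, computed
per subject and then averaged — mean-of-ratios, since cohort E/A values
exceed the ratio of mean peaks.

# Phase normalization and cohort maps

Individual curves are normalized to a fixed template in four sections —
systole, early diastole, diastasis, atrial systole — by a monotone
piecewise-linear time warp and shape-preserving (Fritsch–Carlson
monotone Hermite) resampling; marker times are inserted as knots, so
section boundary values are conserved exactly. The template lengths
default to 350/150/300/200 ms: the 350/650 systole/diastole split is the
cohort average, and the split of diastole into early
diastole/diastasis/atrial systole is a package decision (configurable),
chosen so that typical healthy sections map with modest warps. Averaging
normalized curves across subjects preserves peak amplitude within ~2%
for default-width peaks, whereas naive whole-cycle averaging smears the
atrial peak badly when heart rates differ — the motivation for the
four-section scheme. The 24-segment normalized curves are stacked
anterior → lateral → inferior → septal into the colour grids, one
symmetric colour scale per direction.

# Reproducibility statistics

Between-visit agreement is summarized by the mean ± SD of signed
differences (visit 2 − visit 1, SD with n−1) and Bland–Altman bias ±
2 SD limits. The two-visit simulation keeps each subject's amplitudes
and section-relative timing and changes the heart rate (the day-2 RR
moves by a configurable amount, ±200 ms for the fixed-magnitude mode);
systole length is preserved and diastole absorbs the change, as observed
physiologically. Under these conditions the raw-ms TTP differences of
diastolic and atrial peaks have SDs of tens to >150 ms while the
fixed-length (percentage-based) differences stay within a few ms —
reproducing the central argument for normalizing TTP to systolic and
diastolic length. One curiosity in the published healthy-cohort
reference values is deliberately not used for calibration: the
mid-slice atrial radial TTP reproducibility figures are internally
inconsistent between their percentage and fixed-length forms (the signs
disagree), most plausibly a typographical slip.

# Problem sizes and determinism

The default synthetic cohort runs ten mid-slice subjects on a 64-pixel
grid — a 90 mm crop of the full field of view at the unchanged 1.4 mm
acquired pixel spacing, chosen so the annulus occupies the same pixels
it would in a full-matrix reconstruction while keeping a cohort
simulation in the tens of seconds. Gridding validation uses a 32 × 32
disc with 640 samples per interleave. All stochastic stages are seeded
explicitly; re-running a cohort configuration is bit-identical.

# What the synthetic cohort does not show

The phantom is an idealized annulus: no papillary muscles, no through-
plane motion of anatomy into the slice, no off-resonance or eddy-current
physics (the background is an empirical polynomial), no coil profiles,
and contours are exact rather than manually drawn. Passing tests
demonstrate that the analysis chain is correct and self-consistent under
the stated noise model — not that the in vivo peak values would be
reproduced, which depends on scanner physics and physiology outside the
package's scope. Published cohort velocity tables are used as
calibration ranges for the generator, never as recovery targets.
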