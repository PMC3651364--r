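# spiralPVM

Myocardial tissue **phase velocity mapping** (PVM) encodes tissue
velocity into the phase of MR images. With spiral k-space coverage and
retrospective ECG gating, three-directional myocardial velocities can be
acquired at high temporal (21 ms) and spatial (1.4 mm) resolution in 53
heartbeats, covering 100% of the cardiac cycle — including atrial
systole. spiralPVM is an R package for scientists working with such
acquisitions: it implements the complete analysis chain and a
ground-truthed synthetic left-ventricular phantom so that every stage is
testable without scanner data.

The package covers:

* **Synthetic data** — a moving LV annulus whose velocity field is a
  separable model `v(t, θ, d) = f(t)·m(θ)·g(d)`: periodic raised-cosine
  bump trains carrying the named peaks (S, D, AS longitudinally and
  radially; the biphasic C1/C2 pair and C3 circumferentially), cosine
  regional modulation, a linear transmural gradient, venc-scaled phase
  encoding (φ = π·v/venc), polynomial background phase, Gaussian phase
  noise, a stationary-phantom series, and a respiratory trace with
  dual-navigator acceptance.
* **Spiral reconstruction** — interleaved Archimedean trajectory design,
  an exact direct-DFT forward/adjoint oracle, Kaiser–Bessel convolution
  gridding with trajectory-derived density compensation, and zero-filled
  Fourier interpolation.
* **Velocity reconstruction** — phase differencing
  (`v = venc·Δφ/π`), retrospective-gating interpolation to 60 cardiac
  phases, and stationary-phantom background subtraction.
* **LV geometry** — cylindrical decomposition (longitudinal towards the
  apex, radial towards the slice centre, circumferential clockwise from
  the apex), AHA 6/4-segment and 24-equal-angle partitions, transmural
  thirds on 360 rays, and region-averaged velocity–time curves.
* **Curve analysis** — end systole as the first negative radial peak,
  diastasis and atrial-systole onsets, sub-sample peak refinement, and
  times-to-peak in ms, as percentages of systole/diastole, and as
  fixed-length ms on a 350 ms systole / 650 ms diastole; E/A ratios.
* **Cohort maps** — four-section cardiac-phase normalization (systole,
  early diastole, diastasis, atrial systole), group averaging without
  temporal smearing, and 24-segment × time colour grids.
* **Reproducibility** — signed differences, Bland–Altman limits, and the
  full inter-study reproducibility table with the affine fixed-length
  conversion (3.5/6.5 ms per percent).

## A worked example

Simulate a basal-slice subject, reconstruct its velocities, and quantify
the global radial curve:

```r
library(spiralPVM)

p <- AcquisitionParams(fov = 90, matrixSize = 64)  # cropped FOV, 1.4 mm pixels
model <- buildMotionModel("basal")
model
#> MotionModel (basal slice, RR 1000 ms)
#>   end systole 349 ms; 9 prescribed peaks
#>   S_L: 6.94 cm/s @ 60 ms
#>   D_L: -9.45 cm/s @ 466 ms
#>   AS_L: -2.62 cm/s @ 864 ms
#>   S_R: 2.35 cm/s @ 120 ms
#>   D_R: -4.01 cm/s @ 459 ms
#>   AS_R: -1.41 cm/s @ 857 ms
#>   C1: -2.88 cm/s @ 44 ms
#>   C2: 2.33 cm/s @ 160 ms
#>   C3: -1.58 cm/s @ 410 ms

phantom <- renderVelocityFrames(model, p, gridSize = 64)
bg <- randomBackgroundCoeffs(seed = 7)
encoded <- encodePhases(phantom$velocity, p, backgroundCoeffs = bg,
                        noiseSd = 0.05, seed = 8, mask = phantom$mask)
stationary <- generateStationarySeries(p, gridSize = 64,
                                       times = frameTimes(encoded),
                                       backgroundCoeffs = bg,
                                       noiseSd = 0.05, seed = 9)

v <- phaseDifferenceToVelocity(encoded)
vStat <- smoothBackgroundMap(
  timeAverageSeries(phaseDifferenceToVelocity(stationary)), 3)
v60 <- retroGateInterpolate(subtractBackground(v, vStat), 60)

cont <- annulusContours(model, frameTimes(v60))
geom <- computeGeometry(cont$endo, cont$epi, cont$landmark, c(64, 64),
                        pixelSpacing(p), "basal")
cyl <- toCylindrical(v60, geom)
seg <- assignSegments(geom, "aha")
radial <- regionAverage(cyl, seg, "global", "radial")

tES <- detectEndSystole(radial)       # 350 ms from the R-wave
markers <- detectPhaseMarkers(radial, tES)
detectPeaks(radial, "basal", markers)
#> PeakSet (radial, basal slice):
#>   S_R    2.29 cm/s @ 111.9 ms ( 32.0%, fixed 111.9 ms)
#>   D_R   -3.74 cm/s @ 460.7 ms ( 17.0%, fixed 460.7 ms)
#>   AS_R  -1.36 cm/s @ 856.6 ms ( 77.9%, fixed 856.6 ms)
#>   E/A 2.76
```

The detected radial peaks sit within a few percent of the prescription
(the residual comes from phase noise and the 60-phase linear
interpolation; the cohort pipeline quantifies peaks on the
acquired-resolution curves, where recovery is tighter). Each peak
carries its time from the R-wave, its percentage of systolic or
diastolic length, and the fixed-length conversion used for
heart-rate-independent timing comparisons. `runCohort()` wraps the whole
chain — multi-subject, two-visit, colour maps, reproducibility table,
CSV/JSON report bundle — behind one seeded configuration
(`defaultCohortConfig()`), and `inst/scripts/spiralpvm.R` exposes
`simulate` / `reconstruct` / `run-all` subcommands for shell use.

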