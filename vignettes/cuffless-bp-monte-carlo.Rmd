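---
title: "Cuffless blood-pressure estimation by voxel Monte Carlo photon transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuffless blood-pressure estimation by voxel Monte Carlo photon transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`mcbp` estimates systolic, diastolic and mean arterial pressure (SBP,
DBP, MAP) from fingertip photoplethysmography (PPG) by physical
simulation rather than by regressing pressure on waveform features
directly.  The chain has four parts:

1. **A voxelized finger** -- a mirrored stack of nine tissue layers
   (stratum corneum, epidermis, four dermal sublayers, fat, muscle,
   bone), each carrying an absorption coefficient $\mu_a$, scattering
   coefficient $\mu_s$, anisotropy $g$ and refractive index $n$ at
   905 or 940 nm.  A digital artery runs through the dermis; its lumen
   diameter follows the empirical dilation law
   $d = 0.8531\,p^{0.1023}$ (mm, mmHg), and its absorption is the
   volume-fraction mixture of whole blood and vessel wall for a lumen
   inside a 0.2 mm wall annulus.
2. **Monte Carlo photon transport** through that grid: weighted photon
   packets hop with exponential step lengths
   $l = -\ln\xi/(\mu_a+\mu_s)$, deposit weight by implicit capture,
   scatter by the Henyey--Greenstein phase function, refract/reflect at
   refractive-index boundaries (unpolarized Fresnel), and undergo
   Russian roulette below a weight threshold.  Detected intensity is
   the per-packet-normalized exit weight on the detector side.
3. **A pressure-to-intensity table** built by sweeping arterial
   pressure over the working range 42--200 mmHg, rebuilding the artery
   at each grid point.
4. **Calibration and inversion**: measured PPG beats are filtered
   (zero-phase 6th-order Butterworth bandpass), systolic peaks and
   pulse onsets detected, and the beat intensities -- together with
   signal skewness and kurtosis, BMI and pulse rate -- are mapped onto
   the simulated intensity scale by gradient-boosted regression trees
   (separately for the systolic and diastolic branches).  The
   calibrated intensities are inverted through the monotone table;
   $\mathrm{MAP} = \mathrm{DBP} + (\mathrm{SBP}-\mathrm{DBP})/3$.

Estimates are scored with the standard battery: MAE/RMSE/error SD,
Pearson's $r$ and $R^2$, Bland--Altman bias and limits of agreement,
BHS cumulative-error grading, the AAMI bound (MAE $\le$ 5, SD $\le$ 8
mmHg), and an error-grid classification for MAP.

```{r}
library(mcbp)
grid <- build_voxel_model(finger_geometry(), pressure = 100,
                          wavelength_nm = 940)
sim <- run_simulation(grid, n_photons = 1e4, seed = 1)
sim
```

## Geometry: how the artery is embedded

The dilation law gives lumen radii of 0.63--0.73 mm over the working
range, while the dermal sublayers above the artery total only 0.45 mm:
a cylinder centered at the upper-blood-net/reticular-dermis interface
cannot fit inside the skin at any working pressure.  The builder
therefore *inserts* a dermal band at that interface, sized once for
the top of the working range (`band_pressure = 200`, i.e.
$d(200) + 2w$ thick), and grows the arterial cylinder inside it; band
voxels outside the cylinder are reticular dermis.  Two consequences
matter:

* the slab thickness is **independent of pressure** -- consistent with
  a fixed-thickness finger -- so the pressure signal is carried by the
  conversion of dermis into artery medium, not by a growing slab; and
* the artery voxel count is non-decreasing in pressure by
  construction.

The realized slab thickness (about 10.2 mm for the default mirrored
stack with both artery bands) is reported by the builder rather than
forced to a target value.  The geometry is invariant along the artery
axis, so labels are stored as one x-z cross-section extruded laterally;
the default lateral extent is 10 mm with absorbing (escape) lateral
faces, representing a finite finger width.

## Transport kernel: numerical choices

* Steps are sampled per medium; the dimensionless pathlength is carried
  across voxel faces so heterogeneous voxels are traversed exactly.
* Azimuth is uniform on $[0, 2\pi)$; the Henyey--Greenstein polar
  cosine is clamped to $[-1, 1]$ against round-off.
* The external medium has $n = 1$; specular reflection is applied at
  launch.  Internal faces apply unpolarized Fresnel reflectance with
  Snell refraction, total internal reflection beyond the critical
  angle.
* Russian roulette: threshold $10^{-4}$, survival probability $1/10$.
  Roulette boosts and kills are balanced against the absorbed tally,
  so launched = reflected + transmitted + absorbed + lateral holds to
  floating-point accuracy for every run (the suite checks $10^{-9}$
  relative), not merely in expectation.
* A per-packet event cap ($10^6$) guarantees termination; capped
  packets are counted and their weight goes to the absorbed bin.
* Each packet draws from its own counter-derived xoshiro256+ stream,
  so results are bit-reproducible for a given seed and independent of
  execution order.
* The fluence map tallies **pathlength density** (weight x mm per
  voxel).  This is the quantity whose maximum localizes near the
  artery: the artery medium is far less attenuating than dermis, so
  light accumulates pathlength there.  The absorbed-weight density
  (`absorbed_map()`, fluence x $\mu_a$) instead peaks in the absorbing
  epidermis near the source -- the two maps answer different questions.
* Detected "intensity" for tables is the total exit weight on the
  detector side (the fraction of weight leaving that face); square
  aperture detectors (1 mm default, 0.4 mm reflection offset) are
  available in `run_simulation()` for probe-geometry studies.

## The pressure table at desk-scale photon budgets

Through the full-thickness finger the transmitted fraction is of order
$10^{-5}$ per packet, so a pointwise 1-mmHg table with small Monte
Carlo error is far beyond a desktop photon budget.  The package takes
three measures, all documented as the desk-scale configuration rather
than hidden defaults:

* **Reduced-core geometry** for sweeps (`reduced_finger_geometry()`):
  the skin stack and the artery are kept exact, while fat/muscle/bone
  are thinned to 0.2/0.3/0.4 mm.  The transmitted fraction rises to about
  $2\times10^{-4}$ and carries a strong monotone pressure trend
  (roughly a factor 2.5 across the working range).
* **Common random numbers**: by default every pressure point reuses
  the same per-packet streams.  With a pressure-independent slab,
  histories that never reach the arterial band are identical across
  pressures, which removes shared variance from point-to-point
  differences while keeping the whole table reproducible from one
  seed.
* **Parametric conditioning** (`fit_table()`): even so, the per-point
  noise at, say, $10^5$ packets exceeds the per-10-mmHg trend step, so
  pool-adjacent-violators monotonization (`monotonize()`) leaves exact
  ties (flats) where noise inverted neighbors, and a flat cannot be
  inverted uniquely.  `fit_table()` instead regresses
  $\log I$ on $p^{0.1023}$ -- the arterial dilation exponent -- pooling
  all grid points into a two-parameter strictly monotone curve.  The
  end-to-end pipeline uses this conditioned table; `monotonize()`
  remains the faithful pointwise operation and is idempotent.

A back-of-envelope variance budget: resolving a 1% intensity step at
3.5 standard errors needs about $7\times10^3$ *detected* packets per
point, i.e. several times $10^7$ launched packets per point at
$T \sim 2\times10^{-4}$ -- hence the parametric route.

```{r}
tab_raw <- generate_table(finger_geometry(), wavelength_nm = 940,
                          mode = "transmission", step = 10,
                          n_photons = 1e5, seed = 1)
tab <- fit_table(tab_raw)
invert_intensity(tab, interp_intensity(tab, 120))  # 120
```

## PPG processing

Filtering is a Butterworth bandpass of overall order 6 (0.5--25 Hz for
the 1 kHz public-style profile, 0.5--8 Hz for the 83 Hz self-made
profile), applied forward and backward so peak and onset sample
positions suffer no phase shift.  The signal is padded by odd
reflection over several time constants of the 0.5 Hz low cut before
filtering, so edge transients die inside the padding and a DC input
maps to numerical zero.

Systolic peaks are local maxima above a moving 60th-percentile
threshold (two-beat window), with a refractory separation of 0.4 of
the expected beat period (keep-highest within the refractory
distance); pulse onsets are the peaks of the negated signal.  Beat
intensities are aggregated as the **median** over all beats and
segments (robust to occasional mis-detections); the pulse-rate
estimate is the median inter-peak interval.

Two conventions deserve emphasis:

* **Kurtosis** is excess kurtosis (Fisher convention, normal = 0).
  Quality ranking (`rank_subjects_by_quality()`) uses the summed
  segment skewness only; kurtosis is carried as a calibration feature.
* **Readout**: detection runs on the filtered signal, but the
  intensity *values* at the detected indices are read from the raw
  samples by default.  The 0.5 Hz high-pass removes the DC level, and
  with it the information separating the diastolic intensity scale
  from the beat amplitude; with filtered readout the diastolic
  calibration branch degenerates (cross-validated $R^2$ near zero in
  synthetic experiments), while raw readout keeps both branches
  identifiable.  `readout = "filtered"` is available for sensitivity
  analyses.

## Calibration

The calibration model is a gradient-boosted regression-tree ensemble
(300 trees, depth 4, learning rate 0.05, subsample 0.9 -- all
overridable) mapping the six-feature vector (systolic intensity,
diastolic intensity, skewness, kurtosis, BMI, pulse rate) to the
simulated intensity at the subject's reference SBP or DBP.  Branches
are fitted independently; no per-subject personalization is used.
Reported accuracy is the mean $R^2$ of pooled out-of-fold predictions
over 10-fold cross-validation repeated 3 times with derived seeds.
Targets (magnitude $10^{-4}$) are rescaled to order 1 inside the fit
-- the ensemble's leaf-weight regularization otherwise stalls on such
scales -- and predictions are scaled back; tree ensembles are invariant
to feature scaling, so features are left untouched.

## The synthetic-data generator

The generator stands in for the two recording campaigns the pipeline
targets: a "public"-style profile (1 kHz, three 2.1 s segments per
subject, 100 subjects) and a "selfmade"-style profile (83 Hz, one
240 s recording, 30 subjects).  Covariates are truncated normal with
the published mean/SD/min/max of each profile; SBP and DBP are coupled
by a Gaussian copula (rank correlation 0.8, the strong physiological
association), which keeps the margins exactly truncated normal while
making draws violating SBP > DBP + 10 rare enough to reject without
distorting the margins.

Each beat is the sum of two lognormal-shaped waves (dominant systolic
wave peaking at 25% of the beat, smaller diastolic wave at 55%); the
waveform oscillates between an onset level tied to the intensity table
at the subject's DBP and a peak level tied to the table at the SBP
through an affine device transform (default gain $10^8$, offset
$10^4$, mimicking high-resolution ADC counts).  Subject-level gain and
offset random effects -- scaled by the noise level -- make the
calibration a genuine regression problem rather than a global rescale.
Additive white noise and 0.2--0.4 Hz baseline wander are superimposed;
beat-to-beat timing jitter is 2%.

What passing tests on this generator do and do not show: the
generator's beats are clean two-wave pulses whose amplitudes follow
the simulated table by construction, so end-to-end recovery checks the
*pipeline* (detection, feature extraction, calibration, inversion,
scoring) under controlled noise -- they do not certify accuracy on
real recordings, which carry motion artifacts, pathology-dependent
morphology, device nonlinearities and reference-cuff error that the
generator deliberately omits.

## Evaluation battery

* $R^2$ is the squared Pearson correlation of estimates with
  references (the package-wide convention).
* The AAMI check uses mean *absolute* error $\le 5$ and error SD
  $\le 8$ mmHg, inclusive; the signed bias is reported alongside.  The
  $\ge 85$-subject guideline is an informational flag.
* BHS grades require all three cumulative percentages
  (60/85/95 for A at 5/10/15 mmHg) simultaneously.
* The MAP error grid ships as a package-defined synthetic nested-band
  partition (absolute-or-relative error bands, A through E, boundary
  ties to the better region) in
  `inst/extdata/ega_regions_synthetic.json`; published grids can be
  substituted as a data frame with the same columns.

## Scaled-down study sizes

The test-suite and acceptance-script runs use: $10^4$--$10^5$ packets
per transport check, a 10-mmHg-step table at $10^5$ packets per point
on the reduced-core geometry, and 30-subject self-made-style cohorts
at 0% and 5% noise.  These sizes were chosen so the whole battery runs
on a single workstation core in minutes while keeping Monte Carlo
standard errors small relative to the tolerances being asserted.

## Known limitations

* Layer thicknesses are population constants; no per-subject anatomy.
* No pulsatile intra-beat geometry, polarization, fluorescence or
  time-resolved transport.
* The full-thickness transmission table is noise-dominated at desktop
  photon budgets (see the variance budget above); pointwise tables at
  1 mmHg require cluster-scale computing or the parametric
  conditioning described here.
* Calibration quality on the synthetic cohorts is bounded by the
  subject-level device effects the generator injects; cross-validated
  $R^2$ should be read against that synthetic noise floor, not as a
  claim about clinical data.
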