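# mcbp: cuffless blood pressure from simulated photon transport and PPG

Cuff-based blood-pressure measurement is uncomfortable for continuous
monitoring; fingertip photoplethysmography (PPG) is cheap and
unobtrusive but does not measure pressure directly.  `mcbp` implements
a physics-first route from PPG to pressure for researchers in
biomedical optics and physiological signal processing: instead of
regressing pressure on waveform features, it *simulates* how much
near-infrared light a finger transmits or reflects as a function of
arterial pressure, and reads pressure back off that simulated curve.

The chain:

1. **Finger model.** A voxelized, mirrored stack of nine tissue layers
   (stratum corneum through bone), each with absorption μa, scattering
   μs, anisotropy g and refractive index n at 905/940 nm.  A digital
   artery in the dermis dilates with pressure as
   d = 0.8531·p^0.1023 (mm, mmHg); its absorption mixes whole blood and
   vessel wall by the volume fractions of a lumen inside a 0.2 mm wall.
2. **Monte Carlo transport.** Weighted photon packets hop with step
   l = −ln ξ/(μa+μs), scatter by the Henyey–Greenstein phase function,
   refract at index boundaries (unpolarized Fresnel), and die by
   Russian roulette; exit weights are tallied per face, detector and
   fluence voxel.  Weight conservation holds to 1e−9 per run and
   results are bit-reproducible per seed (Rcpp kernel).
3. **Pressure table.** Sweeping 42–200 mmHg yields the
   pressure→intensity lookup table; `monotonize()` (isotonic
   regression) and `fit_table()` (strictly monotone fit, log-intensity
   affine in p^0.1023) condition it for inversion.
4. **Calibration + inversion.** PPG segments are bandpass filtered
   (zero-phase 6th-order Butterworth), systolic peaks and pulse onsets
   detected, and beat intensities plus skewness/kurtosis/BMI/pulse rate
   are mapped onto the simulated intensity scale by XGBoost (separate
   systolic and diastolic branches, repeated 10-fold CV).  Calibrated
   intensities invert through the table to SBP/DBP;
   MAP = DBP + (SBP − DBP)/3.
5. **Evaluation.** MAE/RMSE/SD/Pearson r/R², Bland–Altman limits of
   agreement, BHS cumulative-error grading, the AAMI bound
   (MAE ≤ 5, SD ≤ 8 mmHg), and a MAP error-grid classification.

A seed-deterministic synthetic cohort/PPG generator (truncated-normal
covariates from the two emulated recording profiles; two-wave beat
morphology coupled to the simulated table) makes the whole pipeline
testable without clinical data.

## Worked example

```r
library(mcbp)

## transport through the default finger at 100 mmHg, 940 nm
grid <- build_voxel_model(finger_geometry(), pressure = 100,
                          wavelength_nm = 940)
run_simulation(grid, n_photons = 2e4, seed = 1)
#> simulation_result: 20000 photons, seed 1
#>   R = 0.47920  T = 0.00000  A = 0.51288  lateral = 0.00792
#>   detector 1 (transmission): 0 +/- 0
#>   detector 2 (reflection): 0.295784 +/- 0.0029

## end-to-end on a 30-subject synthetic cohort, 5% noise
## (table swept on the documented desk-scale reduced-core geometry)
res <- run_pipeline(
  list(table = list(geometry = reduced_finger_geometry(),
                    step = 10, n_photons = 3e4),
       synth = list(profile = "selfmade", n_subjects = 30, noise = 0.05)),
  out_dir = "mcbp_run", seed = 1)
res$report$SBP$metrics[c("mae", "sd", "r")]
#> $mae
#> [1] 0.1094398
#> $sd
#> [1] 0.1360288
#> $r
#> [1] 0.9999403
res$report$SBP$bhs$grade
#> [1] "A"
```

Reading the transport summary: 48% of launched weight re-emerges on
the illuminated face, ~51% is absorbed, ~1% escapes the lateral faces,
and essentially nothing (~1e−5 in expectation, zero detected packets
at this budget) crosses the full 10 mm finger — which is why the
package provides a thinned "reduced-core" geometry
(`reduced_finger_geometry()`) and a parametric table fit for
desk-scale table generation (see the methods vignette).
In the pipeline run, the SBP mean absolute error and error SD are in
mmHg over the 30 synthetic subjects; sub-mmHg values reflect the
noise-controlled synthetic world, not clinical accuracy.

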