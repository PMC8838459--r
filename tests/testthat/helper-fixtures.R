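# Shared fabricated feature/reference tables for calibration and
# estimation tests.

make_features <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    systolic_intensity = runif(n, 1000, 3000),
    diastolic_intensity = runif(n, -1500, -500),
    skewness = rnorm(n, 0.5, 0.2),
    kurtosis = rnorm(n, -0.5, 0.3),
    n_beats = 100, pulse_rate_est = 75,
    stringsAsFactors = FALSE
  )
}

make_refs <- function(features, seed = 2) {
  set.seed(seed)
  n <- nrow(features)
  data.frame(
    subject_id = features$subject_id,
    SBP = round(runif(n, 90, 180), 1),
    DBP = round(runif(n, 50, 85), 1),
    BMI = round(runif(n, 18, 35), 1),
    pulse_rate = round(runif(n, 55, 100), 1),
    stringsAsFactors = FALSE
  )
}

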