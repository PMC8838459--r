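# PPG filtering, beat detection, quality statistics and feature
# extraction.

test_that("bandpass filter removes DC, preserves in-band and rejects out-of-band tones", {
  fs <- 83
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  # pure DC is annihilated
  dc <- bandpass_filter(rep(3.7, length(t)), 0.5, 8, fs = fs)
  expect_lt(max(abs(dc)), 1e-6 * 3.7)
  # 1.5 Hz tone inside the 0.5-8 Hz band keeps its amplitude within 5%
  x <- sin(2 * pi * 1.5 * t)
  y <- bandpass_filter(x, 0.5, 8, fs = fs)
  core <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  expect_lt(abs(max(abs(y[core])) - 1), 0.05)
  # 20 Hz tone is attenuated by at least 40 dB
  x20 <- sin(2 * pi * 20 * t)
  y20 <- bandpass_filter(x20, 0.5, 8, fs = fs)
  expect_lt(20 * log10(max(abs(y20[core]))), -40)
  # linearity
  xr <- x + 0.3 * x20
  expect_equal(bandpass_filter(5 * xr, 0.5, 8, fs = fs),
               5 * bandpass_filter(xr, 0.5, 8, fs = fs),
               tolerance = 1e-9)
  # the public-profile band also works at 1 kHz
  t2 <- seq(0, 2.1 - 1e-3, by = 1e-3)
  y2 <- bandpass_filter(sin(2 * pi * 1.2 * t2), 0.5, 25, fs = 1000)
  expect_true(all(is.finite(y2)))
  expect_error(bandpass_filter(x, 0.5, 50, fs = fs), "Nyquist")
  expect_error(bandpass_filter(x, 0.5, 8, order = 5, fs = fs), "even")
})

test_that("systolic peaks of a sinusoid land on the known maxima", {
  fs <- 100
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * t)
  pk <- detect_systolic_peaks(x, fs, pulse_rate_hint = 60)
  expect_length(pk, 10)
  expected <- 26 + 100 * (0:9)  # t = 0.25 + k
  expect_true(all(abs(pk - expected) <= 1))
  # flat signal yields nothing, with a quality flag
  none <- detect_systolic_peaks(rep(0, 500), fs)
  expect_length(none, 0)
  expect_identical(attr(none, "quality_flag"), "no_peaks")
})

test_that("beat-train detection finds one peak per beat and skips the dicrotic wave", {
  fs <- 100
  x <- synthetic_beat_train(bpm = 72, duration = 60, fs = fs)
  pk <- detect_systolic_peaks(x, fs, pulse_rate_hint = 72)
  expect_true(abs(length(pk) - 72) <= 1)
  on <- detect_pulse_onsets(x, fs, pulse_rate_hint = 72)
  # peaks and onsets strictly alternate
  lab <- rbind(data.frame(i = pk, kind = "p"),
               data.frame(i = on, kind = "o"))
  lab <- lab[order(lab$i), ]
  expect_true(all(lab$kind[-1] != lab$kind[-nrow(lab)]))
  # each detected onset precedes some following peak
  expect_true(all(vapply(on[on < max(pk)],
                         function(o) any(pk > o), TRUE)))
})

test_that("onset detection is the peak detection of the negated signal", {
  fs <- 100
  x <- synthetic_beat_train(bpm = 60, duration = 30, fs = fs)
  expect_identical(detect_pulse_onsets(-x, fs, 60),
                   detect_systolic_peaks(x, fs, 60))
})

test_that("signal quality matches hand-computed moments", {
  # symmetric signal over whole periods has zero skewness
  t <- seq(0, 5 - 0.01, by = 0.01)
  q <- signal_quality(sin(2 * pi * t))
  expect_lt(abs(q$skewness), 1e-10)
  # explicit 5-point series against brute-force moment ratios
  q5 <- signal_quality(c(1, 2, 2, 3, 7))
  expect_equal(q5$skewness, 1.17015863226, tolerance = 1e-9)
  expect_equal(q5$kurtosis, -0.169421487603, tolerance = 1e-9)
  # large normal sample is near 0/0 within 3 asymptotic SEs
  set.seed(5)
  z <- rnorm(1e5)
  qz <- signal_quality(z)
  expect_lt(abs(qz$skewness), 3 * sqrt(6 / 1e5))
  expect_lt(abs(qz$kurtosis), 3 * sqrt(24 / 1e5))
  expect_error(signal_quality(rep(1, 10)), "variance")
})

test_that("subject ranking sums segment skewness with id tie-breaks", {
  seg <- data.frame(
    subject_id = c("s1", "s1", "s2", "s3"),
    skewness = c(1.0, 1.0, 1.0, 3.0))
  expect_identical(rank_subjects_by_quality(seg, 2), c("s3", "s1"))
  expect_identical(rank_subjects_by_quality(seg, 3), c("s3", "s1", "s2"))
  ties <- data.frame(subject_id = c("b", "a"), skewness = c(1, 1))
  expect_identical(rank_subjects_by_quality(ties, 2), c("a", "b"))
  expect_warning(out <- rank_subjects_by_quality(ties, 5), "cohort size")
  expect_length(out, 2)
})

test_that("feature extraction recovers generator amplitudes and pulse rate", {
  tab <- analytic_table()
  subj <- list(subject_id = "X1", SBP = 120, DBP = 80, pulse_rate = 72,
               BMI = 25)
  segs <- generate_ppg(subj, ppg_generator_params(noise_sd = 0,
                                                  wander_amp = 0),
                       tab, profile = "selfmade", seed = 3)
  rec <- subject_record(segs, SBP = 120, DBP = 80, BMI = 25,
                        pulse_rate = 72, subject_id = "X1")
  f <- extract_features(rec)
  v_s <- 1e8 * interp_intensity(tab, 120) + 1e4
  v_d <- 1e8 * interp_intensity(tab, 80) + 1e4
  expect_lt(abs(f$systolic_intensity - v_s) / v_s, 0.01)
  expect_lt(abs(f$diastolic_intensity - v_d) / v_d, 0.01)
  expect_lt(abs(f$pulse_rate_est - 72), 2)
  expect_gte(f$n_beats, 1)
  # feature extraction is invariant to segment order
  segs2 <- generate_ppg(subj, ppg_generator_params(noise_sd = 0.05,
                                                   wander_amp = 0.05),
                        tab, profile = "public", seed = 3)
  reca <- subject_record(segs2, 120, 80, 25, 72, "X1")
  recb <- subject_record(rev(segs2), 120, 80, 25, 72, "X1")
  fa <- extract_features(reca)
  fb <- extract_features(recb)
  expect_equal(fa$systolic_intensity, fb$systolic_intensity)
  expect_equal(fa$skewness, fb$skewness)
  # a constant-segment record fails feature extraction cleanly
  flat <- subject_record(ppg_segment(rep(1, 500), 83), subject_id = "F")
  expect_error(extract_features(flat), "no beats")
})

test_that("single short segment still yields defined features", {
  fs <- 100
  x <- synthetic_beat_train(bpm = 60, duration = 2.5, fs = fs) + 10
  rec <- subject_record(ppg_segment(x, fs), subject_id = "one")
  f <- extract_features(rec, filter_band = c(0.5, 8))
  expect_gte(f$n_beats, 1)
  expect_true(is.finite(f$systolic_intensity))
})
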