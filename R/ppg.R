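# PPG signal processing: zero-phase Butterworth bandpass filtering,
# systolic-peak and pulse-onset detection, signal-quality statistics, and
# per-subject beat-feature extraction.

#' Construct a PPG segment
#'
#' @param samples Numeric vector of raw intensity samples (device units).
#' @param fs Sampling rate, Hz (> 0).
#' @param subject_id,segment_id Identifiers.
#' @return Object of class `ppg_segment`.
#' @export
ppg_segment <- function(samples, fs, subject_id = NA, segment_id = NA) {
  stopifnot(is.numeric(samples), fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs,
                 subject_id = subject_id, segment_id = segment_id),
            class = "ppg_segment")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies a Butterworth bandpass of the stated overall design order
#' forward and backward (zero phase, so detected peak and onset positions
#' are not shifted).  The signal is padded by odd reflection at both ends
#' before filtering so that edge transients -- which matter at the 0.5 Hz
#' low cut -- decay inside the padding, then trimmed back to the input
#' length.  DC is removed by construction.
#'
#' @param x A [ppg_segment()] or numeric vector.
#' @param low_hz,high_hz Band edges, Hz; `0 < low < high < fs/2`.
#' @param order Overall filter order (even, default 6; the underlying
#'   low/high-pass prototype has order `order / 2`).
#' @param fs Sampling rate, Hz (taken from the segment if omitted).
#' @return Filtered numeric vector, same length as the input.
#' @export
bandpass_filter <- function(x, low_hz, high_hz, order = 6, fs = NULL) {
  if (inherits(x, "ppg_segment")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop("fs must be supplied for a bare numeric input")
  if (order %% 2 != 0 || order < 2) stop("order must be a positive even number")
  if (!(low_hz > 0 && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
  if (high_hz >= fs / 2)
    stop("high_hz must be below the Nyquist frequency fs/2")
  bf <- signal::butter(order / 2, c(low_hz, high_hz) / (fs / 2),
                       type = "pass")
  # odd-reflection padding: several time constants of the low cut
  n <- length(x)
  pad <- min(n - 1, ceiling(6 / low_hz * fs))
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(left, x, right)
  yp <- signal::filtfilt(bf, xp)
  yp[seq(pad + 1, pad + n)]
}

adaptive_threshold <- function(x, fs, pulse_rate_hint, prob = 0.6) {
  win <- max(3L, as.integer(round(2 * fs * 60 / pulse_rate_hint)))
  half <- win %/% 2
  n <- length(x)
  # moving quantile on a coarse grid, interpolated to all samples
  centers <- unique(pmin(n, pmax(1, seq(1, n, by = max(1L, half %/% 4)))))
  qs <- vapply(centers, function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    stats::quantile(x[lo:hi], prob, names = FALSE)
  }, numeric(1))
  if (length(centers) == 1) rep(qs, n)
  else stats::approx(centers, qs, xout = seq_len(n), rule = 2)$y
}

#' Detect systolic peaks in a filtered PPG signal
#'
#' Local maxima exceeding an adaptive amplitude threshold (a moving 60th
#' percentile over a two-beat window), subject to a minimum separation of
#' `0.4 * (60 / pulse_rate_hint)` seconds; when two candidates fall
#' within the refractory distance the higher one is kept.
#'
#' @param x Filtered numeric signal.
#' @param fs Sampling rate, Hz.
#' @param pulse_rate_hint Expected pulse rate, beats/min (default 75).
#' @return Ascending integer vector of peak sample indices (empty when no
#'   peak qualifies, with attribute `quality_flag = "no_peaks"`).
#' @export
detect_systolic_peaks <- function(x, fs, pulse_rate_hint = 75) {
  stopifnot(fs > 0, pulse_rate_hint > 0)
  n <- length(x)
  empty <- structure(integer(0), quality_flag = "no_peaks")
  if (n < 3) return(empty)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(cand) == 0) return(empty)
  thr <- adaptive_threshold(x, fs, pulse_rate_hint)
  cand <- cand[x[cand] > thr[cand] + 1e-12 * max(abs(x))]
  if (length(cand) == 0) return(empty)
  min_sep <- 0.4 * (60 / pulse_rate_hint) * fs
  keep <- logical(length(cand))
  taken <- integer(0)
  for (i in order(x[cand], decreasing = TRUE)) {
    if (!any(abs(cand[i] - taken) < min_sep)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  sort(cand[keep])
}

#' Detect pulse onsets in a filtered PPG signal
#'
#' The pulse onset (foot of the beat, the diastolic-intensity landmark)
#' is found by negating the signal and reusing the systolic peak
#' detector, so each onset is a local minimum preceding its paired
#' systolic peak.
#'
#' @inheritParams detect_systolic_peaks
#' @return Ascending integer vector of onset sample indices.
#' @export
detect_pulse_onsets <- function(x, fs, pulse_rate_hint = 75) {
  detect_systolic_peaks(-x, fs, pulse_rate_hint)
}

#' Signal-quality statistics of a PPG signal
#'
#' Sample skewness (third standardized moment) and excess kurtosis
#' (fourth standardized moment minus 3, the Fisher convention), the two
#' statistics used for segment quality ranking and as calibration
#' features.
#'
#' @param samples Numeric vector, length >= 3, nonzero variance.
#' @return Named list with `skewness` and `kurtosis`.
#' @export
signal_quality <- function(samples) {
  if (length(samples) < 3) stop("need at least 3 samples")
  if (stats::var(samples) == 0)
    stop("zero-variance signal: quality statistics undefined")
  list(skewness = e1071::skewness(samples, type = 1),
       kurtosis = e1071::kurtosis(samples, type = 1))
}

#' Rank subjects by summed segment skewness
#'
#' Per-subject quality score is the sum of the skewness of each of the
#' subject's segments; subjects are sorted by descending score (ties
#' broken by subject id) and the top `top_n` are returned.
#'
#' @param segment_skewness Data frame with columns `subject_id` and
#'   `skewness` (one row per segment).
#' @param top_n Number of subjects to select.
#' @return Character vector of selected subject ids, best first.
#' @export
rank_subjects_by_quality <- function(segment_skewness, top_n) {
  stopifnot(all(c("subject_id", "skewness") %in% names(segment_skewness)))
  score <- tapply(segment_skewness$skewness, segment_skewness$subject_id,
                  sum)
  ids <- names(score)
  ord <- order(-unname(score), ids)
  if (top_n > length(ids)) {
    warning("top_n exceeds cohort size; returning all subjects")
    top_n <- length(ids)
  }
  ids[ord][seq_len(top_n)]
}

#' Construct a subject record
#'
#' @param segments List of [ppg_segment()]s.
#' @param SBP,DBP Reference cuff pressures, mmHg (`SBP > DBP`).
#' @param BMI Body-mass index, kg/m^2.
#' @param pulse_rate Reference pulse rate, beats/min.
#' @param subject_id Identifier.
#' @return Object of class `subject_record`.
#' @export
subject_record <- function(segments, SBP = NA_real_, DBP = NA_real_,
                           BMI = NA_real_, pulse_rate = NA_real_,
                           subject_id = NA) {
  if (inherits(segments, "ppg_segment")) segments <- list(segments)
  stopifnot(all(vapply(segments, inherits, TRUE, "ppg_segment")))
  if (!is.na(SBP) && !is.na(DBP) && SBP <= DBP)
    stop("SBP must exceed DBP")
  structure(list(segments = segments, SBP = SBP, DBP = DBP, BMI = BMI,
                 pulse_rate = pulse_rate, subject_id = subject_id),
            class = "subject_record")
}

#' Extract beat features from a subject's PPG segments
#'
#' Filters each segment, detects systolic peaks and pulse onsets, and
#' aggregates the systolic and diastolic (onset) intensities as the
#' median over all beats of all segments.  The pulse rate estimate comes
#' from the median inter-peak interval; skewness and kurtosis are
#' computed on the concatenated raw segments.  Peaks and onsets are
#' detected on the filtered signal; the intensity VALUES at the detected
#' indices are read from the raw samples by default (`readout =
#' "filtered"` reads the filtered signal instead; note the bandpass
#' removes the DC level that separates the systolic and diastolic
#' intensity scales).
#'
#' @param record A [subject_record()].
#' @param filter_band Length-2 numeric, bandpass edges in Hz.
#' @param order Filter order (default 6).
#' @param readout Read beat intensities from the `"raw"` (default) or
#'   `"filtered"` signal at the detected indices.
#' @return Object of class `beat_features`: a list with
#'   `systolic_intensity`, `diastolic_intensity`, `skewness`, `kurtosis`,
#'   `n_beats`, `pulse_rate_est`.
#' @export
extract_features <- function(record, filter_band = c(0.5, 8), order = 6,
                             readout = c("raw", "filtered")) {
  stopifnot(inherits(record, "subject_record"), length(filter_band) == 2)
  readout <- match.arg(readout)
  raw_all <- unlist(lapply(record$segments, `[[`, "samples"))
  if (stats::var(raw_all) == 0)
    stop("no beats detected for subject ", record$subject_id,
         ": constant signal")
  hint <- if (!is.na(record$pulse_rate)) record$pulse_rate else 75
  sys_vals <- dia_vals <- numeric(0)
  intervals <- numeric(0)
  n_beats <- 0L
  for (seg in record$segments) {
    filt <- bandpass_filter(seg, filter_band[1], filter_band[2],
                            order = order)
    src <- if (readout == "raw") seg$samples else filt
    pk <- detect_systolic_peaks(filt, seg$fs, hint)
    on <- detect_pulse_onsets(filt, seg$fs, hint)
    if (length(pk) == 0) next
    n_beats <- n_beats + length(pk)
    sys_vals <- c(sys_vals, src[pk])
    dia_vals <- c(dia_vals, src[on])
    if (length(pk) > 1) intervals <- c(intervals, diff(pk) / seg$fs)
  }
  if (n_beats == 0L)
    stop("no beats detected for subject ", record$subject_id,
         ": feature extraction failed")
  q <- signal_quality(raw_all)
  pr <- if (length(intervals) > 0) 60 / stats::median(intervals) else hint
  structure(list(
    systolic_intensity = stats::median(sys_vals),
    diastolic_intensity = stats::median(dia_vals),
    skewness = q$skewness, kurtosis = q$kurtosis,
    n_beats = n_beats, pulse_rate_est = pr,
    subject_id = record$subject_id
  ), class = "beat_features")
}

#' Extract features for a whole cohort
#'
#' Applies [extract_features()] to each record, dropping (with a message)
#' subjects whose segments yield no detectable beats.
#'
#' @param records List of [subject_record()]s.
#' @inheritParams extract_features
#' @return Data frame with one row per surviving subject: `subject_id`,
#'   `systolic_intensity`, `diastolic_intensity`, `skewness`, `kurtosis`,
#'   `n_beats`, `pulse_rate_est`.
#' @export
extract_cohort_features <- function(records, filter_band = c(0.5, 8),
                                    order = 6, readout = c("raw", "filtered")) {
  readout <- match.arg(readout)
  rows <- lapply(records, function(rec) {
    f <- tryCatch(extract_features(rec, filter_band, order, readout),
                  error = function(e) {
                    message(conditionMessage(e))
                    NULL
                  })
    if (is.null(f)) return(NULL)
    data.frame(subject_id = f$subject_id,
               systolic_intensity = f$systolic_intensity,
               diastolic_intensity = f$diastolic_intensity,
               skewness = f$skewness, kurtosis = f$kurtosis,
               n_beats = f$n_beats, pulse_rate_est = f$pulse_rate_est,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Read PPG segments and covariates from a manifest
#'
#' The manifest CSV lists one row per segment with columns `subject_id`,
#' `segment_id`, `fs`, `file` (CSV with a `value` column, path relative
#' to the manifest).  Cohort covariates come from a separate CSV with
#' columns `subject_id`, `SBP`, `DBP`, `BMI`, `pulse_rate`.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param covariates_path Path to the covariates CSV.
#' @return List of [subject_record()]s.
#' @export
read_ppg_manifest <- function(manifest_path, covariates_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  cov <- utils::read.csv(covariates_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(split(man, man$subject_id), function(rows) {
    segs <- lapply(seq_len(nrow(rows)), function(i) {
      f <- rows$file[i]
      if (!file.exists(f)) f <- file.path(base, rows$file[i])
      ppg_segment(utils::read.csv(f)$value, rows$fs[i],
                  rows$subject_id[i], rows$segment_id[i])
    })
    ci <- cov[match(rows$subject_id[1], cov$subject_id), ]
    subject_record(segs, SBP = ci$SBP, DBP = ci$DBP, BMI = ci$BMI,
                   pulse_rate = ci$pulse_rate,
                   subject_id = rows$subject_id[1])
  })
}
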