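# Synthetic cohorts and PPG recordings emulating the two dataset profiles
# the pipeline targets: a "public"-style profile (1 kHz, three 2.1 s
# segments per subject) and a "selfmade"-style profile (83 Hz, one 240 s
# recording per subject).  Covariates are drawn from truncated normal
# distributions with the profiles' published summary statistics, and beat
# amplitudes are tied to a simulated intensity table through an affine
# device transform, so every stage of the pipeline can be exercised
# end-to-end with known ground truth.

.cohort_profiles <- list(
  public = list(
    fs = 1000, n_segments = 3, duration = 2.1,
    SBP = c(mean = 124.42, sd = 19.65, min = 80, max = 182),
    DBP = c(mean = 69.46, sd = 10.46, min = 42, max = 96),
    BMI = c(mean = 23.23, sd = 3.88, min = 15.94, max = 35.84),
    pulse_rate = c(mean = 73.2, sd = 10.87, min = 52, max = 103)
  ),
  selfmade = list(
    fs = 83, n_segments = 1, duration = 240,
    SBP = c(mean = 104.57, sd = 11.65, min = 81, max = 133),
    DBP = c(mean = 75.8, sd = 6.86, min = 62, max = 96),
    BMI = c(mean = 27.87, sd = 2.96, min = 20.76, max = 34.6),
    pulse_rate = c(mean = 82.47, sd = 10.49, min = 55, max = 108)
  )
)

#' Cohort specification
#'
#' Collects the covariate distributions and recording profile of a
#' synthetic cohort.  Defaults come from the published summary statistics
#' (mean, SD, min, max) of the emulated dataset profiles.
#'
#' @param profile `"selfmade"` (83 Hz, one 240 s segment per subject,
#'   default) or `"public"` (1 kHz, three 2.1 s segments).
#' @param n_subjects Cohort size (default 30 for selfmade, 100 for
#'   public).
#' @param seed Integer seed.
#' @param overrides Optional named list replacing individual covariate
#'   parameter vectors, e.g. `list(SBP = c(mean = 120, sd = 10, min = 90,
#'   max = 150))`.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(profile = c("selfmade", "public"),
                        n_subjects = NULL, seed = 1, overrides = NULL) {
  profile <- match.arg(profile)
  spec <- .cohort_profiles[[profile]]
  spec$profile <- profile
  spec$n_subjects <- if (is.null(n_subjects)) {
    if (profile == "selfmade") 30L else 100L
  } else as.integer(n_subjects)
  spec$seed <- seed
  for (nm in names(overrides)) spec[[nm]] <- overrides[[nm]]
  for (v in c("SBP", "DBP")) {
    if (spec[[v]][["min"]] < 42 || spec[[v]][["max"]] > 200)
      stop(v, " range must lie within the 42-200 mmHg working range")
  }
  class(spec) <- "cohort_spec"
  spec
}

# truncated-normal quantile function (exact margins)
qtruncnorm1 <- function(u, par) {
  a <- stats::pnorm(par[["min"]], par[["mean"]], par[["sd"]])
  b <- stats::pnorm(par[["max"]], par[["mean"]], par[["sd"]])
  if (a >= b) stop("empty truncation region for a covariate")
  stats::qnorm(a + u * (b - a), par[["mean"]], par[["sd"]])
}

rtruncnorm1 <- function(n, par) qtruncnorm1(stats::runif(n), par)

#' Generate a synthetic cohort table
#'
#' Draws SBP, DBP, BMI and pulse rate per subject from truncated normal
#' distributions with the profile's published mean/SD, truncated at the
#' published min/max.  SBP and DBP are coupled through a Gaussian copula
#' (rank correlation ~0.8, the strong physiological SBP-DBP association),
#' which keeps the margins exactly truncated normal while making draws
#' with `SBP <= DBP + 10` rare; such draws are rejected and redrawn.
#' Seed-deterministic.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with `subject_id`, `SBP`, `DBP`, `BMI`,
#'   `pulse_rate`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$SBP[["min"]] > spec$SBP[["max"]] ||
      spec$SBP[["max"]] <= spec$DBP[["min"]] + 10)
    stop("infeasible cohort spec: SBP/DBP truncation regions do not ",
         "admit SBP > DBP + 10")
  set.seed(spec$seed)
  n <- spec$n_subjects
  rho <- 0.8
  sbp <- dbp <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- n - filled
    z1 <- stats::rnorm(m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
    s <- qtruncnorm1(stats::pnorm(z1), spec$SBP)
    d <- qtruncnorm1(stats::pnorm(z2), spec$DBP)
    ok <- s > d + 10
    k <- sum(ok)
    if (k > 0) {
      sbp[filled + seq_len(k)] <- s[ok]
      dbp[filled + seq_len(k)] <- d[ok]
      filled <- filled + k
    }
  }
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    SBP = round(sbp, 1), DBP = round(dbp, 1),
    BMI = round(rtruncnorm1(n, spec$BMI), 2),
    pulse_rate = round(rtruncnorm1(n, spec$pulse_rate), 1),
    stringsAsFactors = FALSE
  )
}

#' PPG generator parameters
#'
#' Beat morphology and noise model of the synthetic PPG generator.  Each
#' beat is the sum of two lognormal-shaped waves (a dominant systolic
#' wave and a smaller diastolic wave); the waveform oscillates between a
#' diastolic level tied to the intensity table at the subject's DBP and a
#' systolic level tied to the table at the subject's SBP through an
#' affine device transform with subject-level random effects (making the
#' downstream tree-ensemble calibration genuinely necessary rather than a
#' single rescale).
#'
#' @param gain,offset Affine device transform from table intensity to
#'   device units.
#' @param noise_sd Additive white-noise SD as a fraction of the beat
#'   amplitude (>= 0).
#' @param wander_amp Baseline-wander amplitude as a fraction of the beat
#'   amplitude; its frequency is drawn per segment from
#'   `wander_freq_hz`.
#' @param wander_freq_hz Length-2 range of wander frequencies, Hz.
#' @param subject_effect_sd Per-subject log-gain / relative-offset SD
#'   multiplying `noise_sd` (default 0.5).
#' @param timing_jitter Beat-to-beat period jitter, fraction (default
#'   0.02, at most 0.03).
#' @param sys_peak_phase Phase of the systolic wave within the beat.
#' @return Object of class `ppg_generator_params`.
#' @export
ppg_generator_params <- function(gain = 1e8, offset = 1e4,
                                 noise_sd = 0.05, wander_amp = 0.05,
                                 wander_freq_hz = c(0.2, 0.4),
                                 subject_effect_sd = 0.5,
                                 timing_jitter = 0.02,
                                 sys_peak_phase = 0.25) {
  stopifnot(gain > 0, noise_sd >= 0, wander_amp >= 0,
            timing_jitter >= 0, timing_jitter <= 0.03)
  structure(list(gain = gain, offset = offset, noise_sd = noise_sd,
                 wander_amp = wander_amp, wander_freq_hz = wander_freq_hz,
                 subject_effect_sd = subject_effect_sd,
                 timing_jitter = timing_jitter,
                 sys_peak_phase = sys_peak_phase),
            class = "ppg_generator_params")
}

# normalized two-wave beat template on phase u in [0, 1): 0 at the onset
# (u = 0), 1 at the systolic peak, small secondary (diastolic) wave
beat_template <- function(u, sys_peak_phase = 0.25) {
  b <- function(u) {
    out <- numeric(length(u))
    pos <- u > 0
    out[pos] <- exp(-log(u[pos] / sys_peak_phase)^2 / (2 * 0.35^2)) +
      0.35 * exp(-log(u[pos] / (2.2 * sys_peak_phase))^2 / (2 * 0.25^2))
    out
  }
  ugrid <- seq(0.001, 0.999, by = 0.001)
  peak <- max(b(ugrid))
  b(u) / peak
}

#' Generate synthetic PPG segments for one subject
#'
#' Produces a beat train at the subject's pulse rate whose per-beat
#' systolic-peak amplitude is `gain * table(SBP) + offset` and whose
#' pulse-onset amplitude is `gain * table(DBP) + offset` (plus
#' noise-scaled per-beat and per-subject perturbations), with additive
#' white noise and sinusoidal baseline wander, sampled according to the
#' profile's rate, duration and segment count.
#'
#' @param subject One row of a [generate_cohort()] table (list or
#'   single-row data frame with `SBP`, `DBP`, `pulse_rate`,
#'   `subject_id`).
#' @param params A [ppg_generator_params()].
#' @param table A monotone [intensity_table()] whose intensity increases
#'   with pressure, covering the subject's pressures.
#' @param profile `"selfmade"` or `"public"`.
#' @param seed Integer seed.
#' @return List of [ppg_segment()]s.
#' @export
generate_ppg <- function(subject, params = ppg_generator_params(),
                         table, profile = c("selfmade", "public"),
                         seed = 1) {
  profile <- match.arg(profile)
  stopifnot(inherits(params, "ppg_generator_params"),
            inherits(table, "intensity_table"))
  prof <- .cohort_profiles[[profile]]
  i_s <- interp_intensity(table, subject$SBP)
  i_d <- interp_intensity(table, subject$DBP)
  if (is.na(i_s) || is.na(i_d))
    stop("subject pressures outside the intensity table range")

  set.seed(seed)
  noise <- params$noise_sd
  # subject-level device effects, scaled by the noise level
  gain_i <- params$gain *
    exp(noise * params$subject_effect_sd * stats::rnorm(1))
  offset_i <- params$offset *
    (1 + noise * params$subject_effect_sd * stats::rnorm(1))
  v_s <- gain_i * i_s + offset_i
  v_d <- gain_i * i_d + offset_i
  amp <- v_s - v_d
  if (amp <= 0)
    stop("intensity table must increase with pressure for PPG synthesis")

  period0 <- 60 / subject$pulse_rate
  lapply(seq_len(prof$n_segments), function(k) {
    n <- round(prof$fs * prof$duration)
    t <- (seq_len(n) - 1) / prof$fs
    # beat onset times with bounded timing jitter
    n_beats <- ceiling(prof$duration / period0) + 2
    periods <- period0 *
      (1 + params$timing_jitter * stats::runif(n_beats, -1, 1))
    onsets <- c(0, cumsum(periods))
    beat_of <- findInterval(t, onsets)
    u <- (t - onsets[beat_of]) / periods[beat_of]
    shape <- beat_template(u, params$sys_peak_phase)
    # per-beat amplitude jitter, scaled by the noise level
    bj <- 1 + 0.3 * noise * stats::rnorm(n_beats)
    x <- v_d + amp * shape * bj[beat_of]
    if (params$wander_amp > 0) {
      f <- stats::runif(1, params$wander_freq_hz[1],
                        params$wander_freq_hz[2])
      phi <- stats::runif(1, 0, 2 * pi)
      x <- x + params$wander_amp * amp * sin(2 * pi * f * t + phi)
    }
    if (noise > 0) x <- x + noise * amp * stats::rnorm(n)
    ppg_segment(x, prof$fs, subject$subject_id, k)
  })
}

#' Generate a cohort of subject records
#'
#' Convenience wrapper: draws a cohort and synthesizes PPG segments for
#' every subject, returning ready-to-process [subject_record()]s.
#'
#' @param spec A [cohort_spec()].
#' @param params A [ppg_generator_params()].
#' @param table A monotone increasing [intensity_table()].
#' @return List with `cohort` (data frame) and `records` (list of
#'   [subject_record()]s).
#' @export
generate_cohort_records <- function(spec = cohort_spec(),
                                    params = ppg_generator_params(),
                                    table) {
  cohort <- generate_cohort(spec)
  records <- lapply(seq_len(nrow(cohort)), function(j) {
    subj <- cohort[j, ]
    segs <- generate_ppg(subj, params, table, spec$profile,
                         seed = spec$seed + 131 * j)
    subject_record(segs, SBP = subj$SBP, DBP = subj$DBP, BMI = subj$BMI,
                   pulse_rate = subj$pulse_rate,
                   subject_id = subj$subject_id)
  })
  list(cohort = cohort, records = records)
}

#' Write a complete end-to-end fixture to disk
#'
#' Generates a cohort, synthesizes its PPG recordings, and writes one CSV
#' per segment plus a manifest CSV, a covariates CSV and a truth CSV (the
#' generating SBP/DBP) -- a full on-disk exercise of the
#' process / calibrate / estimate / evaluate chain.  Regeneration with
#' the same arguments is byte-identical.
#'
#' @param spec A [cohort_spec()].
#' @param table A monotone increasing [intensity_table()].
#' @param noise Noise level: sets both the white-noise SD and the
#'   baseline-wander amplitude of [ppg_generator_params()].
#' @param seed Integer seed (overrides `spec$seed`).
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the written file paths
#'   (`manifest`, `covariates`, `truth`, `segments`).
#' @export
generate_end_to_end_fixture <- function(spec = cohort_spec(), table,
                                        noise = 0.05, seed = spec$seed,
                                        dir) {
  spec$seed <- seed
  params <- ppg_generator_params(noise_sd = noise, wander_amp = noise)
  gen <- generate_cohort_records(spec, params, table)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg_files <- character(0)
  man <- list()
  for (j in seq_along(gen$records)) {
    rec <- gen$records[[j]]
    for (seg in rec$segments) {
      f <- sprintf("%s_seg%d.csv", rec$subject_id, seg$segment_id)
      utils::write.csv(data.frame(value = seg$samples),
                       file.path(dir, f), row.names = FALSE)
      seg_files <- c(seg_files, f)
      man[[length(man) + 1]] <- data.frame(
        subject_id = rec$subject_id, segment_id = seg$segment_id,
        fs = seg$fs, file = f, stringsAsFactors = FALSE)
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, man), manifest, row.names = FALSE)
  covariates <- file.path(dir, "cohort.csv")
  utils::write.csv(gen$cohort, covariates, row.names = FALSE)
  truth <- file.path(dir, "truth.csv")
  utils::write.csv(gen$cohort[, c("subject_id", "SBP", "DBP")], truth,
                   row.names = FALSE)
  invisible(list(manifest = manifest, covariates = covariates,
                 truth = truth,
                 segments = file.path(dir, seg_files)))
}
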