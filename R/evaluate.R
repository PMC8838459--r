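# Blood-pressure estimation from calibrated intensities and the
# evaluation battery: error metrics, Bland-Altman agreement, BHS grading,
# AAMI compliance, and error-grid analysis for MAP.

#' Mean arterial pressure from SBP and DBP
#'
#' `MAP = DBP + (SBP - DBP) / 3`, a convex combination, so MAP always
#' lies between DBP and SBP.
#'
#' @param sbp,dbp Systolic and diastolic pressure, mmHg.
#' @return MAP, mmHg.
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  dbp + (sbp - dbp) / 3
}

#' Estimate SBP, DBP and MAP from calibrated intensities
#'
#' Predicts calibrated systolic and diastolic intensities for each
#' subject, inverts them through the respective monotone intensity
#' tables, and derives MAP.  Out-of-range intensities clamp to the
#' nearest endpoint pressure and are flagged; a subject whose estimated
#' DBP exceeds the estimated SBP is flagged (`inverted`) and reported
#' unmodified.
#'
#' @param model_sys,model_dia Systolic and diastolic
#'   [fit_calibration()] models.
#' @param features Data frame with the calibration feature columns (and
#'   optionally `subject_id`).
#' @param table_sys,table_dia Monotone [intensity_table()]s used for
#'   inversion (typically the same table).
#' @return Data frame with `subject_id`, `SBP_est`, `DBP_est`, `MAP_est`,
#'   `sbp_oor`, `dbp_oor`, `inverted`.
#' @export
estimate_bp <- function(model_sys, model_dia, features, table_sys,
                        table_dia = table_sys) {
  stopifnot(inherits(model_sys, "calibration_model"),
            inherits(model_dia, "calibration_model"))
  i_sys <- predict_calibrated_intensity(model_sys, features)
  i_dia <- predict_calibrated_intensity(model_dia, features)
  sbp <- invert_intensity(table_sys, as.numeric(i_sys))
  dbp <- invert_intensity(table_dia, as.numeric(i_dia))
  data.frame(
    subject_id = if ("subject_id" %in% names(features))
      features$subject_id else seq_along(sbp),
    SBP_est = as.numeric(sbp), DBP_est = as.numeric(dbp),
    MAP_est = mean_arterial_pressure(as.numeric(sbp), as.numeric(dbp)),
    sbp_oor = attr(sbp, "out_of_range"),
    dbp_oor = attr(dbp, "out_of_range"),
    inverted = as.numeric(dbp) > as.numeric(sbp),
    stringsAsFactors = FALSE
  )
}

#' Agreement metrics between reference and estimated pressures
#'
#' MAE, RMSE, standard deviation of the signed errors (n-1 denominator),
#' Pearson's r, and R-squared (the squared Pearson correlation of
#' estimates with references -- the convention used throughout this
#' package).
#'
#' @param reference,estimated Equal-length numeric vectors (mmHg),
#'   length >= 2.
#' @return Named list: `mae`, `rmse`, `sd`, `bias`, `r`, `r2`, `n`.
#'   `r`/`r2` are `NA` when either vector has zero variance.
#' @export
compute_metrics <- function(reference, estimated) {
  stopifnot(length(reference) == length(estimated),
            length(reference) >= 2)
  e <- estimated - reference
  r <- if (stats::sd(reference) == 0 || stats::sd(estimated) == 0)
    NA_real_ else stats::cor(reference, estimated)
  list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)), sd = stats::sd(e),
       bias = mean(e), r = r, r2 = r^2, n = length(e))
}

#' Bland-Altman agreement analysis
#'
#' Differences `estimated - reference`; bias is their mean and the 95%
#' limits of agreement are `bias +/- 1.96 * SD`.
#'
#' @inheritParams compute_metrics
#' @return Named list: `bias`, `sd`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(reference, estimated) {
  stopifnot(length(reference) == length(estimated),
            length(reference) >= 2)
  d <- estimated - reference
  s <- stats::sd(d)
  list(bias = mean(d), sd = s,
       loa_low = mean(d) - 1.96 * s, loa_high = mean(d) + 1.96 * s)
}

.bhs_thresholds <- data.frame(
  grade = c("A", "B", "C"),
  le5 = c(60, 50, 40), le10 = c(85, 75, 65), le15 = c(95, 90, 85)
)

#' BHS cumulative-error grade
#'
#' Cumulative percentages of absolute errors within 5, 10 and 15 mmHg
#' and the British Hypertension Society grade: A requires
#' >= 60/85/95 %, B >= 50/75/90 %, C >= 40/65/85 % (all three conditions
#' simultaneously), otherwise D.
#'
#' @param abs_errors Non-empty vector of absolute errors, mmHg.
#' @return Named list: `pct_le5`, `pct_le10`, `pct_le15`, `grade`.
#' @export
bhs_grade <- function(abs_errors) {
  stopifnot(length(abs_errors) > 0)
  abs_errors <- abs(abs_errors)
  pct <- vapply(c(5, 10, 15),
                function(t) 100 * mean(abs_errors <= t), numeric(1))
  grade <- "D"
  for (i in seq_len(nrow(.bhs_thresholds))) {
    th <- .bhs_thresholds[i, ]
    if (pct[1] >= th$le5 && pct[2] >= th$le10 && pct[3] >= th$le15) {
      grade <- th$grade
      break
    }
  }
  list(pct_le5 = pct[1], pct_le10 = pct[2], pct_le15 = pct[3],
       grade = grade)
}

#' AAMI compliance check
#'
#' Passes when the mean absolute error is at most 5 mmHg and the error
#' standard deviation at most 8 mmHg (inclusive bounds).  The subject
#' count is reported against the standard's >= 85 subject guideline as
#' an informational flag, not a failure condition.
#'
#' @param errors Signed errors, mmHg (non-empty).
#' @param n_subjects Number of subjects behind the errors (default:
#'   `length(errors)`).
#' @return Named list: `pass`, `mae`, `sd`, `n_subjects`,
#'   `meets_subject_count`.
#' @export
aami_check <- function(errors, n_subjects = length(errors)) {
  stopifnot(length(errors) > 0)
  mae <- mean(abs(errors))
  s <- if (length(errors) > 1) stats::sd(errors) else 0
  list(pass = mae <= 5 && s <= 8, mae = mae, sd = s,
       n_subjects = n_subjects, meets_subject_count = n_subjects >= 85)
}

#' Default MAP error-grid region specification
#'
#' A synthetic nested-band partition of the (reference, estimate) plane:
#' each region accepts pairs whose absolute error or relative error is
#' within its band, and the first (clinically best) region containing a
#' pair wins, so boundary points go to the better region and the bands
#' partition the plane.  The defining band edges are packaged in
#' `ega_regions_synthetic.json`; they are a package-defined stand-in for
#' a published grid and can be replaced by the user.
#'
#' @return Data frame with columns `region`, `abs_mmHg`, `rel_pct`
#'   (either bound qualifies; the last region is unbounded).
#' @export
default_ega_regions <- function() {
  path <- system.file("extdata", "ega_regions_synthetic.json",
                      package = "mcbp")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- data.frame(region = raw$region,
                     abs_mmHg = as.numeric(raw$abs_mmHg),
                     rel_pct = as.numeric(raw$rel_pct),
                     stringsAsFactors = FALSE)
  validate_ega_regions(spec)
}

validate_ega_regions <- function(spec) {
  need <- c("region", "abs_mmHg", "rel_pct")
  if (!all(need %in% names(spec)))
    stop("region spec needs columns region, abs_mmHg, rel_pct")
  n <- nrow(spec)
  if (!is.infinite(spec$abs_mmHg[n]) && !is.infinite(spec$rel_pct[n]))
    stop("region spec does not cover the plane: the last region must ",
         "be unbounded")
  if (any(diff(spec$abs_mmHg[-n]) <= 0) || any(diff(spec$rel_pct[-n]) <= 0))
    stop("region bands must be strictly nested (increasing bounds)")
  spec
}

#' Error-grid classification of MAP estimates
#'
#' Assigns each (reference, estimated) MAP pair to exactly one region of
#' the configured error-grid partition (A = clinically equivalent through
#' E = dangerous).  Boundary pairs go to the better (earlier-letter)
#' region.
#'
#' @param reference_map,estimated_map Equal-length MAP vectors, mmHg.
#' @param region_spec Region specification as returned by
#'   [default_ega_regions()].
#' @return List with `region` (factor, per pair) and `counts` (named
#'   vector over all regions, summing to the number of pairs).
#' @export
ega_map_classify <- function(reference_map, estimated_map,
                             region_spec = default_ega_regions()) {
  stopifnot(length(reference_map) == length(estimated_map))
  spec <- validate_ega_regions(region_spec)
  abs_err <- abs(estimated_map - reference_map)
  rel_err <- 100 * abs_err / pmax(abs(reference_map), 1e-12)
  region <- rep(spec$region[nrow(spec)], length(abs_err))
  assigned <- rep(FALSE, length(abs_err))
  for (i in seq_len(nrow(spec))) {
    hit <- !assigned & (abs_err <= spec$abs_mmHg[i] |
                          rel_err <= spec$rel_pct[i])
    region[hit] <- spec$region[i]
    assigned <- assigned | hit
  }
  region <- factor(region, levels = spec$region)
  list(region = region, counts = table(region))
}

#' Full evaluation report for a set of estimates
#'
#' Computes the per-component metric block, Bland-Altman analysis, BHS
#' grade, AAMI compliance and the MAP error grid in one pass.
#'
#' @param estimates Data frame from [estimate_bp()].
#' @param refs Data frame with `subject_id`, `SBP`, `DBP`.
#' @param region_spec Error-grid regions (default packaged spec).
#' @return Nested list keyed by component (`SBP`, `DBP`, `MAP`) plus
#'   `ega_map`.
#' @export
evaluate_estimates <- function(estimates, refs,
                               region_spec = default_ega_regions()) {
  df <- merge(estimates, refs[, c("subject_id", "SBP", "DBP")],
              by = "subject_id")
  df$MAP <- mean_arterial_pressure(df$SBP, df$DBP)
  out <- list()
  for (comp in c("SBP", "DBP", "MAP")) {
    ref <- df[[comp]]
    est <- df[[paste0(comp, "_est")]]
    out[[comp]] <- list(
      metrics = compute_metrics(ref, est),
      bland_altman = bland_altman(ref, est),
      bhs = bhs_grade(est - ref),
      aami = aami_check(est - ref)
    )
  }
  out$ega_map <- ega_map_classify(df$MAP, df$MAP_est, region_spec)
  out$n <- nrow(df)
  out
}

#' Blood-pressure category labels
#'
#' Standard clinical categories from SBP/DBP (normal, elevated, stage 1
#' and 2 hypertension, hypertensive crisis); a reading is assigned the
#' more severe category of its two components.
#'
#' @param sbp,dbp Pressures in mmHg.
#' @return Character vector of category labels.
#' @export
bp_category <- function(sbp, dbp) {
  mapply(function(s, d) {
    if (s > 180 || d > 120) "hypertensive crisis"
    else if (s >= 140 || d >= 90) "hypertension stage 2"
    else if (s >= 130 || d >= 80) "hypertension stage 1"
    else if (s >= 120) "elevated"
    else "normal"
  }, sbp, dbp, USE.NAMES = FALSE)
}
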