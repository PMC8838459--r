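# Estimation arithmetic and the evaluation battery.

test_that("MAP is the stated convex combination of SBP and DBP", {
  expect_equal(mean_arterial_pressure(120, 80), 93 + 1 / 3,
               tolerance = 1e-12)
  expect_equal(mean_arterial_pressure(110, 110), 110)
  set.seed(1)
  s <- runif(100, 90, 200); d <- runif(100, 40, 89)
  m <- mean_arterial_pressure(s, d)
  expect_true(all(m >= pmin(s, d) & m <= pmax(s, d)))
})

test_that("metric block matches a brute-force 4-point computation", {
  r <- c(100, 110, 120, 130)
  e <- c(102, 108, 123, 128)
  m <- compute_metrics(r, e)
  expect_equal(m$mae, 2.25)
  expect_equal(m$rmse, 2.29128784748, tolerance = 1e-9)
  expect_equal(m$sd, 2.62995563968, tolerance = 1e-9)
  expect_equal(m$r, 0.979490172659, tolerance = 1e-9)
  expect_equal(m$r2, m$r^2)
  # identity and constant-offset cases
  id <- compute_metrics(r, r)
  expect_equal(id$mae, 0); expect_equal(id$rmse, 0); expect_equal(id$r, 1)
  off <- compute_metrics(r, r + 2)
  expect_equal(off$mae, 2); expect_equal(off$sd, 0)
  expect_true(is.na(compute_metrics(c(1, 1), c(1, 2))$r))
})

test_that("metric identities hold on random data", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    r <- rnorm(n, 120, 15); e <- r + rnorm(n, 1, 5)
    m <- compute_metrics(r, e)
    expect_gte(m$rmse, m$mae - 1e-12)
    expect_equal(m$rmse^2, m$bias^2 + m$sd^2 * (n - 1) / n,
                 tolerance = 1e-9)
  }
})

test_that("Bland-Altman bias and limits of agreement are as defined", {
  r <- c(100, 120)
  ba0 <- bland_altman(r, r)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0); expect_equal(ba0$loa_high, 0)
  # differences {-1, +1}: bias 0, sd sqrt(2), LoA +/- 1.96 sqrt(2)
  ba <- bland_altman(c(100, 120), c(99, 121))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$loa_low, -1.96 * sqrt(2))
  set.seed(3)
  rr <- rnorm(30, 120, 10); ee <- rr + rnorm(30, 2, 4)
  bb <- bland_altman(rr, ee)
  expect_true(bb$loa_low <= bb$bias && bb$bias <= bb$loa_high)
})

test_that("BHS grading applies the cumulative thresholds", {
  all0 <- bhs_grade(rep(0, 10))
  expect_equal(c(all0$pct_le5, all0$pct_le10, all0$pct_le15),
               c(100, 100, 100))
  expect_identical(all0$grade, "A")
  # exactly at the A thresholds (60/85/95) still grades A
  e <- c(rep(4, 60), rep(9, 25), rep(14, 10), rep(20, 5))
  g <- bhs_grade(e)
  expect_equal(c(g$pct_le5, g$pct_le10, g$pct_le15), c(60, 85, 95))
  expect_identical(g$grade, "A")
  expect_identical(bhs_grade(rep(12, 5))$grade, "D")
  expect_equal(bhs_grade(rep(12, 5))$pct_le15, 100)
  # all three conditions must hold: 100% <=5 but poor <=10 tail is not A
  mix <- c(rep(1, 70), rep(30, 30))
  expect_identical(bhs_grade(mix)$grade, "D")
  # monotonicity: pointwise smaller errors never worsen the grade
  set.seed(4)
  for (i in 1:10) {
    e1 <- abs(rnorm(40, 6, 5))
    e2 <- e1 * runif(40, 0, 1)
    g1 <- bhs_grade(e1)$grade; g2 <- bhs_grade(e2)$grade
    expect_lte(match(g2, c("A", "B", "C", "D")),
               match(g1, c("A", "B", "C", "D")))
  }
  # cumulative percentages are non-decreasing across thresholds
  gg <- bhs_grade(abs(rnorm(50, 5, 5)))
  expect_true(gg$pct_le5 <= gg$pct_le10 && gg$pct_le10 <= gg$pct_le15)
})

test_that("AAMI check uses inclusive MAE and SD bounds", {
  expect_true(aami_check(rep(0, 10))$pass)
  # published-scale errors (MAE ~3.3, SD ~6) pass
  set.seed(8)
  e <- rnorm(100, 0, 4.2)
  chk0 <- aami_check(e)
  expect_true(chk0$mae <= 5 && chk0$sd <= 8 && chk0$pass)
  # MAE just over the bound fails even with tiny SD
  expect_false(aami_check(c(5.01, 5.01))$pass)
  # boundary values pass inclusively: errors {5, -5} give MAE exactly 5
  chk <- aami_check(c(5, -5))
  expect_equal(chk$mae, 5)
  expect_lte(chk$sd, 8)
  expect_true(chk$pass)
  expect_false(aami_check(c(20, -20))$pass)
  expect_true(aami_check(rep(0, 90))$meets_subject_count)
  expect_false(aami_check(rep(0, 30))$meets_subject_count)
})

test_that("MAP error grid partitions the plane with boundary ties to the better region", {
  ref <- c(90, 100, 110)
  cls <- ega_map_classify(ref, ref)
  expect_true(all(cls$region == "A"))
  expect_equal(sum(cls$counts), 3)
  # a far-off pair lands worse than B
  far <- ega_map_classify(70, 140)
  expect_gt(match(as.character(far$region), c("A", "B", "C", "D", "E")), 2)
  # boundary point: exactly 5 mmHg absolute error is still region A
  b <- ega_map_classify(100, 105)
  expect_identical(as.character(b$region), "A")
  # counts over random pairs always sum to n
  set.seed(5)
  rr <- runif(200, 60, 140); ee <- rr + rnorm(200, 0, 15)
  cc <- ega_map_classify(rr, ee)
  expect_equal(sum(cc$counts), 200)
  # an invalid (non-partition) spec is rejected
  bad <- data.frame(region = c("A", "B"), abs_mmHg = c(5, 10),
                    rel_pct = c(10, 20))
  expect_error(ega_map_classify(100, 100, bad), "cover the plane")
})

test_that("estimates invert calibrated intensities through the table", {
  tab <- analytic_table()
  feats <- data.frame(
    subject_id = c("a", "b"),
    systolic_intensity = c(1500, 2500),
    diastolic_intensity = c(-700, -1200),
    skewness = c(0.4, 0.6), kurtosis = c(-0.2, 0.1),
    BMI = c(24, 28), pulse_rate = c(70, 80), stringsAsFactors = FALSE)
  refs <- data.frame(subject_id = c("a", "b"), SBP = c(120, 140),
                     DBP = c(80, 90), BMI = c(24, 28),
                     pulse_rate = c(70, 80), stringsAsFactors = FALSE)
  # build enough rows to fit: replicate with jitter
  set.seed(6)
  big_feats <- make_features(25, seed = 71)
  big_refs <- make_refs(big_feats, seed = 72)
  ds_s <- build_calibration_dataset(big_feats, big_refs, tab, "systolic")
  ds_d <- build_calibration_dataset(big_feats, big_refs, tab, "diastolic")
  m_s <- fit_calibration(ds_s, seed = 1)
  m_d <- fit_calibration(ds_d, seed = 2)
  est <- estimate_bp(m_s, m_d, ds_s[, setdiff(names(ds_s), "target")],
                     tab)
  expect_identical(nrow(est), 25L)
  expect_true(all(est$MAP_est >= pmin(est$SBP_est, est$DBP_est) &
                    est$MAP_est <= pmax(est$SBP_est, est$DBP_est)))
  expect_true(all(est$SBP_est >= 42 & est$SBP_est <= 200))
})

test_that("evaluation report is internally consistent", {
  set.seed(7)
  n <- 30
  refs <- data.frame(subject_id = sprintf("S%02d", 1:n),
                     SBP = runif(n, 95, 175), DBP = runif(n, 55, 90))
  est <- data.frame(subject_id = refs$subject_id,
                    SBP_est = refs$SBP + rnorm(n, 0, 3),
                    DBP_est = refs$DBP + rnorm(n, 0, 2))
  est$MAP_est <- mean_arterial_pressure(est$SBP_est, est$DBP_est)
  rep <- evaluate_estimates(est, refs)
  expect_equal(rep$n, n)
  expect_equal(sum(rep$ega_map$counts), n)
  for (comp in c("SBP", "DBP", "MAP")) {
    b <- rep[[comp]]$bhs
    expect_true(b$pct_le5 <= b$pct_le10 && b$pct_le10 <= b$pct_le15)
    expect_equal(rep[[comp]]$metrics$sd, rep[[comp]]$bland_altman$sd)
  }
})

test_that("blood-pressure categories follow the clinical cutpoints", {
  expect_identical(bp_category(115, 75), "normal")
  expect_identical(bp_category(124, 75), "elevated")
  expect_identical(bp_category(135, 75), "hypertension stage 1")
  expect_identical(bp_category(118, 85), "hypertension stage 1")
  expect_identical(bp_category(150, 95), "hypertension stage 2")
  expect_identical(bp_category(185, 100), "hypertensive crisis")
})
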