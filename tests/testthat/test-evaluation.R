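obs_at <- function(pid, hours) {
  tibble::tibble(patient_id = pid, time = ts("2020-01-01 00:00") + hours * 3600)
}
event_at <- function(pid, hours, kind = "DETERIORATION") {
  tibble::tibble(patient_id = pid, kind = kind,
                 event_time = ts("2020-01-01 00:00") + hours * 3600,
                 evidence = "")
}

test_that("forward-window labels follow the 24 h rule and exclusions", {
  obs <- obs_at("A", c(0, 10, 30, 40))
  ev <- event_at("A", 34)
  lab <- label_observations(obs, ev)
  # t=0: event 34 h away -> 0; t=10: 24 h away -> 1; t=30: 4 h -> 1; t=40 excluded
  expect_equal(lab$label, c(0, 1, 1))
  expect_equal(attr(lab, "n_excluded"), 1)

  # event at t+10 h labels 1; no events labels all 0
  expect_equal(label_observations(obs_at("A", 0), event_at("A", 10))$label, 1)
  none <- label_observations(obs, event_at("B", 10))
  expect_equal(none$label, rep(0, 4))

  # kind filtering: infection events do not label deterioration analyses
  lab2 <- label_observations(obs, event_at("A", 34, kind = "INFECTION"),
                             kind = "DETERIORATION")
  expect_equal(lab2$label, rep(0, 4))
  expect_error(label_observations(obs, ev, horizon_hours = 0), "positive")
})

test_that("shrinking the horizon never increases positive labels", {
  set.seed(12)
  obs <- dplyr::bind_rows(lapply(1:20, function(i) {
    obs_at(paste0("P", i), sort(runif(10, 0, 72)))
  }))
  ev <- dplyr::bind_rows(lapply(sample(1:20, 8), function(i) {
    event_at(paste0("P", i), runif(1, 10, 80))
  }))
  prev <- Inf
  for (h in c(48, 24, 12, 6, 1)) {
    n_pos <- sum(label_observations(obs, ev, horizon_hours = h)$label)
    expect_lte(n_pos, prev)
    prev <- n_pos
  }
})

test_that("midrank AUC equals brute-force pair counting with ties half", {
  # worked example: pos {3, 2}, neg {2, 1} -> 0.875
  expect_equal(compute_auc(c(3, 2, 2, 1), c(1, 1, 0, 0))$auc, 0.875)
  # perfect ranking and all-tied degenerate cases
  expect_equal(compute_auc(c(5, 4, 1, 0), c(1, 1, 0, 0))$auc, 1)
  const <- compute_auc(rep(2, 10), rep(c(0, 1), 5))
  expect_equal(const$auc, 0.5)
  expect_equal(const$variance, 0)
  expect_error(compute_auc(1:5, rep(1, 5)), "degenerate_labels")

  set.seed(33)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- sample(0:8, n, replace = TRUE) + rbinom(n, 1, 0.5) * 0.5
    expect_equal(compute_auc(scores, labels)$auc, naive_auc(scores, labels))
  }
})

test_that("AUC and DeLong variance match the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(91)
  labels <- rbinom(300, 1, 0.3)
  labels[1:2] <- c(0, 1)
  a <- rnorm(300) + labels
  b <- rnorm(300) + 0.5 * labels
  ra <- pROC::roc(labels, a, quiet = TRUE, direction = "<")
  mine <- compute_auc(a, labels)
  expect_equal(mine$auc, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  expect_equal(sqrt(mine$variance), sqrt(pROC::var(ra)), tolerance = 1e-9)
  ref <- pROC::roc.test(ra, pROC::roc(labels, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  cmp <- delong_compare(a, b, labels)
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(cmp$z, as.numeric(ref$statistic), tolerance = 1e-9)
})

test_that("DeLong self-comparison gives difference 0 and p exactly 1", {
  set.seed(2)
  labels <- rbinom(80, 1, 0.4); labels[1:2] <- c(0, 1)
  scores <- rnorm(80)
  cmp <- delong_compare(scores, scores, labels)
  expect_identical(cmp$difference, 0)
  expect_identical(cmp$p_value, 1)
})

test_that("DeLong separates a perfect score from a constant at moderate n", {
  set.seed(14)
  labels <- rep(c(1, 0), each = 50)
  perfect <- 1 - labels + rep(c(2, 0), each = 50)  # separates classes
  constant <- rep(1, 100)
  cmp <- delong_compare(perfect, constant, labels)
  expect_equal(cmp$difference, 0.5)
  expect_lt(cmp$p_value, 0.05)
})

test_that("threshold metrics reproduce hand counts and boundary behavior", {
  scores <- c(5, 4, 3, 2, 1, 0)
  labels <- c(1, 1, 0, 1, 0, 0)
  tm <- threshold_metrics(scores, labels, thresholds = 3)
  # alerts: 5,4,3 -> TP 2, FP 1; below: 2,1,0 -> FN 1, TN 2
  expect_equal(tm$tp, 2); expect_equal(tm$fp, 1)
  expect_equal(tm$fn, 1); expect_equal(tm$tn, 2)
  expect_equal(tm$sensitivity, 2 / 3)
  expect_equal(tm$specificity, 2 / 3)
  expect_equal(tm$ppv, 2 / 3); expect_equal(tm$npv, 2 / 3)

  lo <- threshold_metrics(scores, labels, thresholds = -1)
  expect_equal(lo$sensitivity, 1); expect_equal(lo$specificity, 0)
  hi <- threshold_metrics(scores, labels, thresholds = 99)
  expect_equal(hi$sensitivity, 0); expect_equal(hi$specificity, 1)
  # counts always partition the observations
  tm_all <- threshold_metrics(scores, labels)
  expect_true(all(tm_all$tp + tm_all$fp + tm_all$tn + tm_all$fn == 6))
})

test_that("threshold sweep is monotone and integrates to the AUC", {
  set.seed(77)
  scores <- sample(0:10, 400, replace = TRUE)
  labels <- rbinom(400, 1, plogis(scores - 5))
  labels[1:2] <- c(0, 1)
  tm <- threshold_metrics(scores, labels)
  expect_true(all(diff(tm$sensitivity) <= 1e-12))
  expect_true(all(diff(tm$specificity) >= -1e-12))
  # trapezoid over the full ROC sweep equals the midrank AUC
  fpr <- c(1, 1 - tm$specificity, 0)
  tpr <- c(1, tm$sensitivity, 0)
  o <- order(fpr, tpr)
  auc_trap <- sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
  expect_equal(auc_trap, compute_auc(scores, labels)$auc, tolerance = 1e-9)
})

test_that("efficiency curve endpoints and monotonicity", {
  const <- efficiency_curve(rep(3, 8), c(1, 0, 1, 0, 0, 0, 0, 1))
  expect_equal(nrow(const), 1)
  expect_equal(const$alert_fraction, 1)
  expect_equal(const$sensitivity, 1)

  scores <- c(9, 8, 7, 3, 2, 1)
  labels <- c(1, 1, 1, 0, 0, 0)
  eff <- efficiency_curve(scores, labels)
  expect_equal(eff$alert_fraction[eff$threshold == 7], 0.5)
  expect_equal(eff$sensitivity[eff$threshold == 7], 1)
  expect_equal(eff$alert_fraction[nrow(eff)], 1)
  expect_equal(eff$sensitivity[nrow(eff)], 1)
  expect_true(all(diff(eff$sensitivity) >= 0))
})

test_that("cohort summary reproduces printed-count percentages", {
  # groups shaped like the study's printed counts
  n_total <- 19611; n_event <- 43
  enc <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n_total)),
    admit_time = ts("2020-01-01 00:00"),
    discharge_time = ts("2020-01-04 00:00"),
    death_time = ts(NA),
    age_years = 27, bmi = 31,
    hypertensive_disorder = FALSE, diabetes = FALSE,
    race_ethnicity = "Black")
  event_ids <- enc$patient_id[seq_len(n_event)]
  enc$hypertensive_disorder[seq_len(12)] <- TRUE                 # 12/43
  enc$hypertensive_disorder[n_event + seq_len(1102)] <- TRUE     # 1102/19568
  enc$diabetes[seq_len(4)] <- TRUE                               # 4/43
  enc$death_time[seq_len(3)] <- ts("2020-01-03 00:00")           # 3/43
  co <- tiny_cohort()
  co$encounters <- enc
  ev <- tibble::tibble(patient_id = event_ids, kind = "DETERIORATION",
                       event_time = ts("2020-01-02 00:00"), evidence = "")
  s <- summarize_cohort(co, ev)
  pick <- function(var) s[s$variable == var & is.na(s$level), ]
  expect_equal(pick("n")$pct_outcome, 0.2)
  expect_equal(pick("hypertensive_disorder")$pct_outcome, 27.9)
  expect_equal(pick("hypertensive_disorder")$pct_no_outcome, 5.6)
  expect_equal(pick("diabetes")$pct_outcome, 9.3)
  expect_equal(pick("mortality")$pct_outcome, 7.0)
  expect_lt(pick("hypertensive_disorder")$p_value, 0.001)

  # single-patient group: medians equal that patient's values, tests NA-safe
  co2 <- tiny_cohort()
  ev2 <- tibble::tibble(patient_id = "A", kind = "DETERIORATION",
                        event_time = ts("2020-01-02 00:00"), evidence = "")
  s2 <- summarize_cohort(co2, ev2)
  expect_equal(s2$median_outcome[s2$variable == "age_years"], 27)
})

test_that("compare_all_systems bundles AUCs, pairwise tests, curves", {
  set.seed(55)
  n <- 300
  lab <- tibble::tibble(
    patient_id = "x", time = ts("2020-01-01 00:00") + seq_len(n) * 60,
    label = rbinom(n, 1, 0.2))
  lab$label[1:2] <- c(0, 1)
  lab$S1 <- rnorm(n) + 2 * lab$label
  lab$S2 <- rnorm(n) + lab$label
  lab$S3 <- lab$S1
  cmp <- compare_all_systems(lab, systems = c("S1", "S2", "S3"))
  expect_equal(nrow(cmp$auc), 3)
  expect_equal(nrow(cmp$delong), 3)          # choose(3, 2)
  expect_true(isSymmetric(cmp$delong_p))
  expect_equal(unname(diag(cmp$delong_p)), rep(1, 3))
  # identical columns compare with p = 1
  expect_equal(cmp$delong_p["S1", "S3"], 1)
  cmp2 <- compare_all_systems(lab, systems = c("S1", "S2"))
  expect_equal(nrow(cmp2$delong), 1)
})
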