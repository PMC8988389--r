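snap_row <- function(...) {
  tibble::tibble(patient_id = "X", time = ts("2020-01-01 10:00"), ...)
}

test_that("shipped configs load, validate, and describe the five systems", {
  cfgs <- default_score_configs()
  expect_named(cfgs, c("MEWS", "NEWS", "MEOWS", "MEWC", "MEWT"))
  expect_equal(cfgs$MEWS$rule, "SUM_POINTS")
  expect_equal(length(unique(cfgs$MEWS$bands$variable)), 5)
  expect_equal(cfgs$MEOWS$rule, "RED_YELLOW")
  expect_equal(cfgs$MEWC$rule, "ANY_CRITERION")
  expect_equal(cfgs$MEWT$rule, "SEVERE_NONSEVERE")
  expect_error(load_score_config("foo"), "unknown")
})

test_that("config validation rejects overlaps, gaps, unknown variables", {
  cfg <- load_score_config("mews")
  # two bands closed at the same point overlap
  cfg$bands$upper_closed[cfg$bands$variable == "HR" &
                           cfg$bands$upper == 51] <- TRUE
  expect_error(validate_score_config(cfg), "overlap")

  cfg2 <- load_score_config("mews")
  cfg2$bands <- cfg2$bands[!(cfg2$bands$variable == "HR" &
                               cfg2$bands$lower == 51), ]
  expect_error(validate_score_config(cfg2), "gap")

  cfg3 <- load_score_config("mews")
  cfg3$bands$variable[1] <- "XYZ"
  expect_error(validate_score_config(cfg3), "unknown_variable")
})

test_that("score configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_score_config(load_score_config("meows"), path)
  cfg <- load_score_config(path)
  expect_equal(cfg$system, "MEOWS")
  expect_equal(cfg$trigger_threshold, 2L)
  snap <- snap_row(HR = 125)
  expect_equal(score_meows(snap, cfg)$ordinal_value, 2L)
})

test_that("MEWS worked examples score exactly", {
  expect_equal(score_mews(snap_row(RR = 12, HR = 80, SBP = 120, TEMP = 36.8,
                                   AVPU = 0))$ordinal_value, 0L)
  r <- score_mews(snap_row(RR = 22, HR = 115, SBP = 85, TEMP = 38.6, AVPU = 1))
  expect_equal(r$ordinal_value, 8L)   # 2+2+1+2+1
  expect_equal(r$completeness, 1)
  r2 <- score_mews(snap_row(HR = 101))
  expect_equal(r2$ordinal_value, 1L)  # boundary: 101 in the 101-110 band
  expect_equal(r2$completeness, 0.2)
})

test_that("NEWS worked examples score exactly", {
  expect_equal(score_news(snap_row(RR = 16, SPO2 = 98, SUPP_O2 = 0,
                                   TEMP = 37.0, SBP = 120, HR = 70,
                                   AVPU = 0))$ordinal_value, 0L)
  expect_equal(score_news(snap_row(RR = 25, SPO2 = 92, SUPP_O2 = 1,
                                   TEMP = 39.2, SBP = 95, HR = 112,
                                   AVPU = 0))$ordinal_value, 13L)  # 3+2+2+2+2+2
  expect_equal(score_news(snap_row(SPO2 = 95))$ordinal_value, 1L)  # 94-95 band
})

test_that("MEOWS red/yellow combination rule", {
  all_normal <- snap_row(RR = 14, HR = 80, SBP = 120, DBP = 70, TEMP = 37,
                         SPO2 = 99, AVPU = 0)
  r0 <- score_meows(all_normal)
  expect_equal(r0$ordinal_value, 0L)
  expect_false(r0$trigger)

  red <- score_meows(snap_row(HR = 125))
  expect_equal(red$ordinal_value, 2L)
  expect_true(red$trigger)

  one_yellow <- score_meows(snap_row(HR = 105))
  expect_equal(one_yellow$ordinal_value, 1L)
  expect_false(one_yellow$trigger)

  two_yellow <- score_meows(snap_row(HR = 105, RR = 24))
  expect_equal(two_yellow$ordinal_value, 2L)
  expect_true(two_yellow$trigger)
})

test_that("MEWC counts criteria; any single criterion triggers", {
  expect_equal(score_mewc(snap_row(RR = 14, HR = 80, SBP = 120, DBP = 70,
                                   SPO2 = 99))$ordinal_value, 0L)
  one <- score_mewc(snap_row(SBP = 165))
  expect_equal(one$ordinal_value, 1L)
  expect_true(one$trigger)
  two <- score_mewc(snap_row(SBP = 165, SPO2 = 93))
  expect_equal(two$ordinal_value, 2L)
  expect_true(two$trigger)
  # unquantified urine (0) is not oliguria; a quantified low urine is
  expect_equal(score_mewc(snap_row(URINE_OUT = 0))$ordinal_value, 0L)
  expect_equal(score_mewc(snap_row(URINE_OUT = 300))$ordinal_value, 1L)
})

test_that("MEWT severe/non-severe combination rule and derived MAP", {
  expect_false(score_mewt(snap_row(RR = 16, HR = 80, SBP = 120, DBP = 70,
                                   TEMP = 37, SPO2 = 99))$trigger)
  sev <- score_mewt(snap_row(HR = 135))
  expect_equal(sev$ordinal_value, 2L)
  expect_true(sev$trigger)
  ns1 <- score_mewt(snap_row(TEMP = 38.2))
  expect_equal(ns1$ordinal_value, 1L)
  expect_false(ns1$trigger)
  ns2 <- score_mewt(snap_row(TEMP = 38.2, RR = 26))
  expect_equal(ns2$ordinal_value, 2L)
  expect_true(ns2$trigger)
  # MAP = (SBP + 2*DBP)/3 = 50 -> severe
  low_map <- score_mewt(snap_row(SBP = 90, DBP = 30))
  expect_true(low_map$trigger)
  expect_gte(low_map$ordinal_value, 2L)
})

test_that("vectorized scoring equals naive per-variable band scan", {
  snaps <- random_snapshot(150, seed = 202)
  for (cfg in default_score_configs()) {
    got <- score_snapshots(snaps, cfg)$ordinal_value
    want <- vapply(seq_len(nrow(snaps)),
                   function(i) naive_score(as.list(snaps[i, ]), cfg),
                   numeric(1))
    expect_equal(as.numeric(got), want, info = cfg$system)
  }
})

test_that("trigger/ordinal equivalences hold on random snapshots", {
  snaps <- random_snapshot(200, seed = 7)
  meows <- score_snapshots(snaps, load_score_config("meows"))
  expect_equal(meows$trigger, meows$ordinal_value >= 2)
  mewt <- score_snapshots(snaps, load_score_config("mewt"))
  expect_equal(mewt$trigger, mewt$ordinal_value >= 2)
  mewc <- score_snapshots(snaps, load_score_config("mewc"))
  expect_equal(mewc$trigger, mewc$ordinal_value >= 1)
})

test_that("raising HR never decreases any ordinal; dropping a variable never raises a sum score", {
  base <- snap_row(RR = 16, HR = 60, SBP = 120, DBP = 70, TEMP = 37,
                   SPO2 = 99, AVPU = 0, SUPP_O2 = 0)
  for (cfg in default_score_configs()) {
    prev <- -Inf
    for (hr in c(60, 80, 100, 105, 112, 121, 125, 131, 140, 180)) {
      s <- base
      s$HR <- hr
      val <- score_snapshots(s, cfg)$ordinal_value
      expect_gte(val, prev)
      prev <- val
    }
  }
  abn <- snap_row(RR = 28, HR = 130, SBP = 85, TEMP = 39.5, AVPU = 2,
                  SPO2 = 91, SUPP_O2 = 1)
  for (sys in c("mews", "news")) {
    cfg <- load_score_config(sys)
    full <- score_snapshots(abn, cfg)$ordinal_value
    for (var in unique(cfg$bands$variable)) {
      s <- abn
      s[[var]] <- NA_real_
      expect_lte(score_snapshots(s, cfg)$ordinal_value, full)
    }
  }
})

test_that("score_all is one row per snapshot per system, deterministic", {
  snaps <- random_snapshot(6, seed = 9)
  res <- score_all(snaps)
  expect_equal(nrow(res), 30)
  expect_equal(nrow(score_all(snaps[0, ])), 0)
  expect_identical(res, score_all(snaps))
  # fully-missing snapshot scores 0 with completeness 0
  empty <- tibble::tibble(patient_id = "X", time = ts("2020-01-01 10:00"))
  r <- score_mews(empty)
  expect_equal(r$ordinal_value, 0L)
  expect_equal(r$completeness, 0)
})

test_that("persistence filter keeps only sustained triggers", {
  sc <- tibble::tibble(
    patient_id = "A", system = "MEWC",
    time = ts("2020-01-01 08:00") + c(0, 10, 60) * 60,
    ordinal_value = c(1L, 1L, 1L),
    trigger = c(TRUE, TRUE, TRUE),
    completeness = 1)
  out <- apply_persistence_filter(sc, minutes = 20)
  expect_equal(out$trigger, c(FALSE, TRUE, FALSE))
})

test_that("surrogate risk model: determinism, degenerate labels, drift recovery", {
  expect_error(fit_surrogate_risk_model(random_snapshot(10, 1), rep(0, 10)),
               "degenerate_labels")

  sim <- simulate_cohort(sim_config(n_patients = 250, seed = 31,
                                    drift_scale = 2))
  snaps <- assemble_snapshots(sim$cohort)
  out <- detect_outcomes(sim$cohort)
  lab <- label_observations(snaps, out)
  expect_gt(sum(lab$label), 5)
  m1 <- fit_surrogate_risk_model(lab, lab$label, seed = 42, ntree = 100)
  m2 <- fit_surrogate_risk_model(lab, lab$label, seed = 42, ntree = 100)
  expect_identical(predict_risk(m1, lab), predict_risk(m2, lab))
  expect_gt(m1$cv_auc, 0.5)
  expect_true(all(predict_risk(m1, lab) >= 0 & predict_risk(m1, lab) <= 1))
})
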