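enc_row <- function(pid = "A", admit = "2020-01-01 08:00",
                    discharge = "2020-01-10 08:00", death = NA) {
  tibble::tibble(patient_id = pid, admit_time = ts(admit),
                 discharge_time = ts(discharge), death_time = ts(death),
                 age_years = 28, bmi = 30, hypertensive_disorder = FALSE,
                 diabetes = FALSE, race_ethnicity = "Black")
}

cohort_with <- function(encounters, locations,
                        meds = NULL, cultures = NULL) {
  obsews:::new_cohort(
    encounters = encounters, locations = locations,
    vitals = tibble::tibble(patient_id = character(), time = ts(character()),
                            variable = character(), value = numeric()),
    labs = tibble::tibble(patient_id = character(), time = ts(character()),
                          analyte = character(), value = numeric()),
    meds = meds %||% tibble::tibble(patient_id = character(),
                                    time = ts(character()),
                                    is_antibiotic = logical(),
                                    route = character()),
    cultures = cultures %||% tibble::tibble(patient_id = character(),
                                            order_time = ts(character())))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("direct ward-to-ICU transfer is detected at ICU entry", {
  co <- cohort_with(enc_row(), make_locations(
    "A", c("WARD", "ICU"),
    c("2020-01-01 08:00", "2020-01-03 08:00"),
    c("2020-01-03 08:00", "2020-01-10 08:00")))
  ev <- detect_deterioration(co)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_time, ts("2020-01-03 08:00"))
  expect_equal(ev$kind, "DETERIORATION")
})

test_that("ward-to-L&D-to-ICU qualifies only within the 24 h grace window", {
  qualifying <- cohort_with(enc_row(), make_locations(
    "A", c("WARD", "LND", "ICU"),
    c("2020-01-01 08:00", "2020-01-03 08:00", "2020-01-03 14:00"),
    c("2020-01-03 08:00", "2020-01-03 14:00", "2020-01-10 08:00")))
  ev <- detect_deterioration(qualifying)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_time, ts("2020-01-03 14:00"))

  too_long <- cohort_with(enc_row(), make_locations(
    "A", c("WARD", "LND", "ICU"),
    c("2020-01-01 08:00", "2020-01-03 08:00", "2020-01-04 14:00"),
    c("2020-01-03 08:00", "2020-01-04 14:00", "2020-01-10 08:00")))
  expect_equal(nrow(detect_deterioration(too_long)), 0)  # 30 h dwell

  never_ward <- cohort_with(enc_row(), make_locations(
    "A", c("LND", "ICU"),
    c("2020-01-01 08:00", "2020-01-03 08:00"),
    c("2020-01-03 08:00", "2020-01-10 08:00")))
  expect_equal(nrow(detect_deterioration(never_ward)), 0)
})

test_that("death during or after ward care counts; only first event emitted", {
  died <- cohort_with(
    enc_row(discharge = "2020-01-05 12:00", death = "2020-01-05 12:00"),
    make_locations("A", "WARD", "2020-01-01 08:00", "2020-01-05 12:00"))
  ev <- detect_deterioration(died)
  expect_equal(ev$event_time, ts("2020-01-05 12:00"))
  expect_equal(ev$evidence, "DEATH")

  # ICU transfer then death: the transfer (first event) is the outcome
  both <- cohort_with(
    enc_row(discharge = "2020-01-08 00:00", death = "2020-01-08 00:00"),
    make_locations("A", c("WARD", "ICU"),
                   c("2020-01-01 08:00", "2020-01-02 08:00"),
                   c("2020-01-02 08:00", "2020-01-08 00:00")))
  ev2 <- detect_deterioration(both)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$event_time, ts("2020-01-02 08:00"))

  # idempotence: rerunning the detector yields the same single event
  expect_identical(detect_deterioration(both), ev2)
})

test_that("antibiotic day ledger truncates to calendar days idempotently", {
  e <- enc_row(admit = "2020-01-01 08:00", discharge = "2020-01-05 20:00")
  meds <- tibble::tibble(
    patient_id = "A",
    time = ts(c("2020-01-01 08:30", "2020-01-01 20:00", "2020-01-02 10:00",
                "2020-01-03 10:00", "2020-01-04 10:00")),
    is_antibiotic = TRUE,
    route = c("IV", "IV", "PO", "PO", "PO"))
  led <- build_antibiotic_ledger(meds, e)
  expect_equal(nrow(led), 5)           # admit day through discharge day
  expect_equal(sum(led$iv_abx), 1)     # two IV doses on one day flag once
  expect_equal(led$any_abx, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # non-antibiotic meds are ignored
  meds2 <- meds
  meds2$is_antibiotic <- FALSE
  expect_false(any(build_antibiotic_ledger(meds2, e)$iv_abx))
})

test_that("infection rule: worked four-day and discharge-censored traces", {
  day0 <- ts("2020-01-01 00:30")
  mk <- function(iv_offsets, po_offsets, culture_offset, discharge_day) {
    e <- enc_row(admit = "2020-01-01 08:00",
                 discharge = format(day0 + discharge_day * 86400 + 6 * 3600,
                                    "%Y-%m-%d %H:%M"))
    meds <- tibble::tibble(
      patient_id = "A",
      time = c(day0 + iv_offsets * 86400 + 9 * 3600,
               day0 + po_offsets * 86400 + 9 * 3600),
      is_antibiotic = TRUE,
      route = c(rep("IV", length(iv_offsets)), rep("PO", length(po_offsets))))
    cultures <- tibble::tibble(patient_id = "A",
                               order_time = day0 + culture_offset * 86400 + 11 * 3600)
    list(ledger = build_antibiotic_ledger(meds, e), cultures = cultures, enc = e)
  }

  # culture day 3, IV day 4, IV/PO days 4-7 -> infection at culture order
  f <- mk(iv_offsets = 4, po_offsets = 5:7, culture_offset = 3, discharge_day = 10)
  ev <- detect_infection(f$ledger, f$cultures, f$enc)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_time, f$cultures$order_time)

  # streak too short, not discharge-censored -> none
  f2 <- mk(4, 5, 3, discharge_day = 9)
  expect_equal(nrow(detect_infection(f2$ledger, f2$cultures, f2$enc)), 0)

  # same short streak but discharge day 6: covered through day before discharge
  f3 <- mk(4, 5, 3, discharge_day = 6)
  expect_equal(nrow(detect_infection(f3$ledger, f3$cultures, f3$enc)), 1)

  # IV antibiotics without any culture order -> none
  e <- enc_row()
  meds <- tibble::tibble(patient_id = "A",
                         time = day0 + (0:6) * 86400 + 9 * 3600,
                         is_antibiotic = TRUE, route = "IV")
  led <- build_antibiotic_ledger(meds, e)
  expect_equal(nrow(detect_infection(led, tibble::tibble(
    patient_id = character(), order_time = ts(character())), e)), 0)

  # IV start 3 days after culture: outside the +/- 2 day window
  f4 <- mk(6, 7:9, 3, discharge_day = 12)
  expect_equal(nrow(detect_infection(f4$ledger, f4$cultures, f4$enc)), 0)
})

test_that("infection detector agrees with exhaustive day enumeration", {
  set.seed(881)
  day0 <- ts("2020-03-01 00:00")
  for (rep_i in 1:300) {
    discharge_day <- sample(3:20, 1)
    n_iv <- sample(0:4, 1)
    n_po <- sample(0:8, 1)
    n_cult <- sample(0:2, 1)
    iv_days <- sort(unique(sample(0:discharge_day, n_iv, replace = TRUE)))
    po_days <- sort(unique(sample(0:discharge_day, n_po, replace = TRUE)))
    cult_days <- sort(unique(sample(0:discharge_day, n_cult, replace = TRUE)))
    e <- enc_row(admit = format(day0 + 3600, "%Y-%m-%d %H:%M"),
                 discharge = format(day0 + discharge_day * 86400 + 7200,
                                    "%Y-%m-%d %H:%M"))
    meds <- tibble::tibble(
      patient_id = "A",
      time = day0 + c(iv_days, po_days) * 86400 + 10 * 3600,
      is_antibiotic = TRUE,
      route = c(rep("IV", length(iv_days)), rep("PO", length(po_days))))
    cultures <- tibble::tibble(patient_id = "A",
                               order_time = day0 + cult_days * 86400 + 11 * 3600)
    led <- build_antibiotic_ledger(meds, e)
    got <- nrow(detect_infection(led, cultures, e)) > 0
    d0 <- obsews:::cal_day(e$admit_time)
    want <- naive_infection(iv_days + obsews:::cal_day(day0),
                            unique(c(iv_days, po_days)) + obsews:::cal_day(day0),
                            cult_days + obsews:::cal_day(day0),
                            obsews:::cal_day(e$discharge_time))
    expect_equal(got, want, info = paste("replicate", rep_i))
  }
})

test_that("shifting all timestamps by whole days shifts event times equally", {
  co <- cohort_with(enc_row(), make_locations(
    "A", c("WARD", "ICU"),
    c("2020-01-01 08:00", "2020-01-03 08:00"),
    c("2020-01-03 08:00", "2020-01-10 08:00")),
    meds = tibble::tibble(patient_id = "A",
                          time = ts("2020-01-02 09:00") + (0:4) * 86400,
                          is_antibiotic = TRUE,
                          route = c("IV", rep("PO", 4))),
    cultures = tibble::tibble(patient_id = "A",
                              order_time = ts("2020-01-02 11:00")))
  base <- detect_outcomes(co)
  shift <- 5 * 86400
  co2 <- co
  for (tcol in c("admit_time", "discharge_time")) {
    co2$encounters[[tcol]] <- co2$encounters[[tcol]] + shift
  }
  co2$locations$start_time <- co2$locations$start_time + shift
  co2$locations$end_time <- co2$locations$end_time + shift
  co2$meds$time <- co2$meds$time + shift
  co2$cultures$order_time <- co2$cultures$order_time + shift
  shifted <- detect_outcomes(co2)
  expect_equal(shifted$event_time, base$event_time + shift)
  expect_equal(shifted$kind, base$kind)
})
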