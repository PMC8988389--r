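# Independent brute-force oracles and small fixture builders. These are
# deliberately naive (O(n^2) loops, exhaustive enumeration) so the tested
# implementations are checked against a different computational path.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# O(m*n) pair-counting AUC with ties counted one-half
naive_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# per-variable linear band scan, independent of the vectorized engine
naive_score <- function(snapshot_row, config) {
  level_weight <- c(YELLOW = 1, RED = 2, NONSEVERE = 1, SEVERE = 2,
                    CRITERION = 1)
  total <- 0
  for (var in unique(config$bands$variable)) {
    v <- if (var == "MAP") {
      if (is.null(snapshot_row$SBP) || is.null(snapshot_row$DBP) ||
          is.na(snapshot_row$SBP) || is.na(snapshot_row$DBP)) NA_real_
      else (snapshot_row$SBP + 2 * snapshot_row$DBP) / 3
    } else if (is.null(snapshot_row[[var]])) NA_real_ else snapshot_row[[var]]
    if (is.na(v)) next
    vb <- config$bands[config$bands$variable == var, ]
    for (b in seq_len(nrow(vb))) {
      lo_ok <- if (vb$lower_closed[b]) v >= vb$lower[b] else v > vb$lower[b]
      hi_ok <- if (vb$upper_closed[b]) v <= vb$upper[b] else v < vb$upper[b]
      if (lo_ok && hi_ok) {
        total <- total + if (config$rule == "SUM_POINTS") vb$points[b] else
          level_weight[[vb$level[b]]]
        break
      }
    }
  }
  total
}

# exhaustive enumeration of the infection rule over day sets
naive_infection <- function(iv_days, any_days, culture_days, discharge_day) {
  for (cd in culture_days) {
    for (d0 in iv_days) {
      if (abs(d0 - cd) > 2) next
      need <- seq(d0, min(d0 + 3, discharge_day - 1))
      if (length(need) == 0) need <- d0
      if (all(need %in% any_days)) return(TRUE)
    }
  }
  FALSE
}

# random snapshot rows spanning normal and abnormal physiology
random_snapshot <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    patient_id = sprintf("R%03d", seq_len(n)),
    time = ts("2020-06-01 08:00") + seq_len(n) * 3600,
    RR = sample(c(NA, 4:45), n, replace = TRUE),
    HR = sample(c(NA, 30:180), n, replace = TRUE),
    TEMP = sample(c(NA, seq(33, 41, by = 0.1)), n, replace = TRUE),
    SBP = sample(c(NA, 60:230), n, replace = TRUE),
    DBP = sample(c(NA, 30:130), n, replace = TRUE),
    SPO2 = sample(c(NA, 80:100), n, replace = TRUE),
    AVPU = sample(c(NA, 0:3), n, replace = TRUE),
    SUPP_O2 = sample(c(NA, 0, 1), n, replace = TRUE),
    URINE_OUT = sample(c(NA, 0, 100, 300, 420, 600, 1200), n, replace = TRUE),
    FHR = sample(c(NA, 100:200), n, replace = TRUE)
  )
}

# minimal consistent cohort: one ward-only patient charted twice
tiny_cohort <- function() {
  enc <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    admit_time = ts(c("2020-01-01 08:00", "2020-01-02 09:00", "2020-01-03 10:00")),
    discharge_time = ts(c("2020-01-04 08:00", "2020-01-05 09:00", "2020-01-06 10:00")),
    death_time = ts(c(NA, NA, NA)),
    age_years = c(27, 31, 24), bmi = c(31, 28, 35),
    hypertensive_disorder = c(FALSE, TRUE, FALSE),
    diabetes = c(FALSE, FALSE, FALSE),
    race_ethnicity = c("Black", "White", "Hispanic"))
  loc <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    unit = "WARD",
    start_time = enc$admit_time,
    end_time = enc$discharge_time)
  vit <- tibble::tibble(
    patient_id = c("A", "A", "B"),
    time = ts(c("2020-01-01 10:00", "2020-01-01 14:00", "2020-01-02 12:00")),
    variable = c("HR", "RR", "HR"),
    value = c(82, 18, 90))
  obsews:::new_cohort(
    encounters = enc, locations = loc, vitals = vit,
    labs = tibble::tibble(patient_id = character(), time = ts(character()),
                          analyte = character(), value = numeric()),
    meds = tibble::tibble(patient_id = character(), time = ts(character()),
                          is_antibiotic = logical(), route = character()),
    cultures = tibble::tibble(patient_id = character(),
                              order_time = ts(character())))
}

# write a cohort's six CSVs with arbitrary row tweaks applied first
write_cohort_fixture <- function(dir, vitals_extra = NULL) {
  co <- tiny_cohort()
  if (!is.null(vitals_extra)) co$vitals <- dplyr::bind_rows(co$vitals, vitals_extra)
  write_cohort(co, dir)
}

make_locations <- function(pid, units, starts, ends) {
  tibble::tibble(patient_id = pid, unit = units,
                 start_time = ts(starts), end_time = ts(ends))
}
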