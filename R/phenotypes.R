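# Outcome phenotyping over ADT, medication and culture event streams.
#
# Deterioration: ward -> ICU transfer (direct, or via labor & delivery with
# ICU entry within 24 h of leaving the ward) or death during/after ward care
# without an ICU transfer. Direct L&D -> ICU transfers that never touched the
# ward do not count.
#
# Infection: IV antibiotics within 2 calendar days before or after a blood
# culture order, followed by IV/oral antibiotics on >= 4 consecutive calendar
# days or on every day up to the day before discharge.

cal_day <- function(t) as.integer(floor(as.numeric(t) / 86400))

empty_outcomes <- function() {
  tibble(patient_id = character(), kind = character(),
         event_time = as.POSIXct(character(), tz = "UTC"),
         evidence = character())
}

#' Detect the deterioration composite outcome
#'
#' Scans each patient's ordered location intervals for the first qualifying
#' ward-to-ICU transfer: a WARD interval immediately followed by ICU, or a
#' WARD -> LND -> ICU chain with ICU entry no more than `lnd_grace_hours`
#' after leaving the ward. A death during or after ward care with no
#' qualifying ICU transfer is an event at the death time. At most one event
#' (the first) is emitted per encounter.
#'
#' @param cohort An `ews_cohort` with validated locations and encounters.
#' @param lnd_grace_hours Maximum hours between leaving the ward and ICU
#'   entry for the via-labor-and-delivery clause (default 24).
#' @return Tibble of outcome events: `patient_id`, `kind = "DETERIORATION"`,
#'   `event_time`, `evidence` (transfer chain or death).
#' @export
detect_deterioration <- function(cohort, lnd_grace_hours = 24) {
  loc <- cohort$locations |> arrange(.data$patient_id, .data$start_time)
  enc <- cohort$encounters
  by_pat <- split(loc, loc$patient_id)
  rows <- lapply(enc$patient_id, function(pid) {
    li <- by_pat[[pid]]
    e <- enc[enc$patient_id == pid, ][1, ]
    event_time <- NULL
    evidence <- NULL
    if (!is.null(li) && nrow(li) > 0) {
      units <- li$unit
      for (i in seq_len(nrow(li))) {
        if (units[i] != "WARD") next
        if (i + 1 <= nrow(li) && units[i + 1] == "ICU") {
          event_time <- li$start_time[i + 1]
          evidence <- "WARD->ICU"
          break
        }
        if (i + 2 <= nrow(li) && units[i + 1] == "LND" && units[i + 2] == "ICU") {
          gap_h <- as.numeric(difftime(li$start_time[i + 2], li$end_time[i],
                                       units = "hours"))
          if (gap_h <= lnd_grace_hours) {
            event_time <- li$start_time[i + 2]
            evidence <- sprintf("WARD->LND->ICU (%.1f h)", gap_h)
            break
          }
        }
      }
    }
    if (is.null(event_time) && !is.na(e$death_time)) {
      # death without qualifying ICU transfer, during or after ward care
      had_ward <- !is.null(li) && any(li$unit == "WARD" &
                                        li$start_time <= e$death_time)
      if (had_ward) {
        event_time <- e$death_time
        evidence <- "DEATH"
      }
    }
    if (is.null(event_time)) return(NULL)
    tibble(patient_id = pid, kind = "DETERIORATION",
           event_time = event_time, evidence = evidence)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty_outcomes())
  out |> arrange(.data$event_time, .data$patient_id)
}

#' Build a calendar-day antibiotic ledger for one encounter
#'
#' Truncates antibiotic administrations to calendar days and flags, for each
#' day from admission to discharge, whether any IV antibiotic and whether any
#' IV-or-oral antibiotic was given.
#'
#' @param meds Medication events for one patient (tibble with `time`,
#'   `is_antibiotic`, `route`).
#' @param encounter One-row encounter tibble.
#' @return Tibble with one row per calendar day of the stay: `day` (integer
#'   day index), `iv_abx`, `any_abx`, and attribute `discharge_day`.
#' @export
build_antibiotic_ledger <- function(meds, encounter) {
  d0 <- cal_day(encounter$admit_time)
  d1 <- cal_day(encounter$discharge_time)
  days <- seq(d0, d1)
  abx <- meds[meds$is_antibiotic, , drop = FALSE]
  abx_days <- cal_day(abx$time)
  ledger <- tibble(
    day = days,
    iv_abx = days %in% abx_days[abx$route == "IV"],
    any_abx = days %in% abx_days
  )
  attr(ledger, "discharge_day") <- d1
  ledger
}

infection_qualifies <- function(ledger, culture_day, discharge_day) {
  # any IV day within +/- 2 calendar days of the culture whose IV/PO streak
  # runs 4 consecutive days or through the day before discharge
  iv_days <- ledger$day[ledger$iv_abx]
  cand <- iv_days[abs(iv_days - culture_day) <= 2]
  for (d0 in cand) {
    need <- seq(d0, min(d0 + 3, discharge_day - 1))
    if (length(need) == 0) need <- d0
    if (all(need %in% ledger$day[ledger$any_abx])) return(TRUE)
  }
  FALSE
}

#' Detect the infection outcome for one encounter
#'
#' Applies the antibiotic/blood-culture temporal rule to one patient's
#' ledger and culture orders. The event time is the earliest qualifying
#' culture order.
#'
#' @param ledger Day ledger from [build_antibiotic_ledger()].
#' @param cultures Culture orders for the patient (tibble with `order_time`).
#' @param encounter One-row encounter tibble.
#' @param all_episodes If `TRUE`, emit every qualifying culture order at
#'   least one day apart; default reports only the first.
#' @return Tibble of `INFECTION` outcome events (possibly zero rows).
#' @export
detect_infection <- function(ledger, cultures, encounter,
                             all_episodes = FALSE) {
  if (nrow(cultures) == 0) return(empty_outcomes())
  discharge_day <- attr(ledger, "discharge_day")
  cultures <- cultures |> arrange(.data$order_time)
  hits <- list()
  last_day <- -Inf
  for (i in seq_len(nrow(cultures))) {
    cd <- cal_day(cultures$order_time[i])
    if (cd - last_day < 1 && length(hits) > 0) next
    if (infection_qualifies(ledger, cd, discharge_day)) {
      hits <- c(hits, list(tibble(
        patient_id = encounter$patient_id, kind = "INFECTION",
        event_time = cultures$order_time[i],
        evidence = sprintf("culture day %d within 2 d of IV antibiotics", cd))))
      last_day <- cd
      if (!all_episodes) break
    }
  }
  if (length(hits) == 0) return(empty_outcomes())
  bind_rows(hits)
}

#' Detect infection outcomes for a whole cohort
#' @param cohort An `ews_cohort`.
#' @param all_episodes Passed to [detect_infection()].
#' @return Tibble of `INFECTION` outcome events across patients.
#' @export
detect_infection_cohort <- function(cohort, all_episodes = FALSE) {
  enc <- cohort$encounters
  meds_by <- split(cohort$meds, cohort$meds$patient_id)
  cul_by <- split(cohort$cultures, cohort$cultures$patient_id)
  empty_meds <- cohort$meds[0, ]
  empty_cul <- cohort$cultures[0, ]
  rows <- lapply(seq_len(nrow(enc)), function(i) {
    e <- enc[i, ]
    cul <- cul_by[[e$patient_id]]
    if (is.null(cul) || nrow(cul) == 0) return(NULL)
    meds <- meds_by[[e$patient_id]] %||% empty_meds
    ledger <- build_antibiotic_ledger(meds, e)
    detect_infection(ledger, cul, e, all_episodes = all_episodes)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty_outcomes())
  out |> arrange(.data$event_time, .data$patient_id)
}

#' Phenotype all outcomes for a cohort
#' @param cohort An `ews_cohort`.
#' @return Tibble of `DETERIORATION` and `INFECTION` events.
#' @export
detect_outcomes <- function(cohort) {
  bind_rows(detect_deterioration(cohort), detect_infection_cohort(cohort))
}
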