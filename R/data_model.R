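#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median quantile rnorm rlnorm runif rbinom sd var setNames
#' @importFrom utils head tail
NULL

# Closed vocabularies for the long-format event streams. AVPU and SUPP_O2 are
# stored numerically (A/V/P/U -> 0/1/2/3, FALSE/TRUE -> 0/1) so threshold
# bands apply uniformly.
VITAL_VARIABLES <- c("RR", "HR", "TEMP", "SBP", "DBP", "SPO2",
                     "AVPU", "SUPP_O2", "URINE_OUT", "FHR")
LAB_ANALYTES <- c("WBC", "BUN", "CREATININE", "AST", "ALT",
                  "HEMOGLOBIN", "PLATELETS")
UNIT_LEVELS <- c("WARD", "LND", "ICU", "OTHER")
AVPU_LEVELS <- c(A = 0, V = 1, P = 2, U = 3)

#' Default physiologic plausibility bounds
#'
#' Rows outside these bounds are rejected at read time and never enter
#' scoring. Bounds are deliberately wide (they exclude charting errors, not
#' clinical abnormality) and can be overridden via the `bounds` argument of
#' [read_cohort()].
#'
#' @return A tibble with columns `variable`, `lower`, `upper`.
#' @export
default_bounds <- function() {
  tibble::tribble(
    ~variable,    ~lower, ~upper,
    "RR",              0,     80,
    "HR",             20,    250,
    "TEMP",           30,     43,
    "SBP",            30,    300,
    "DBP",            10,    200,
    "SPO2",           50,    100,
    "AVPU",            0,      3,
    "SUPP_O2",         0,      1,
    "URINE_OUT",       0,  10000,
    "FHR",            50,    250,
    "WBC",             0,    200,
    "BUN",             0,    300,
    "CREATININE",      0,     30,
    "AST",             0,  20000,
    "ALT",             0,  20000,
    "HEMOGLOBIN",      0,     25,
    "PLATELETS",       0,   3000,
  )
}

parse_time <- function(x) {
  # ISO-8601, minute resolution, single implicit timezone per cohort (UTC).
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  out
}

format_time <- function(x) format(x, "%Y-%m-%d %H:%M", tz = "UTC")

cohort_file_names <- function() {
  c(encounters = "encounters.csv", locations = "locations.csv",
    vitals = "vitals.csv", labs = "labs.csv", meds = "meds.csv",
    cultures = "cultures.csv")
}

required_columns <- function() {
  list(
    encounters = c("patient_id", "admit_time", "discharge_time", "death_time",
                   "age_years", "bmi", "hypertensive_disorder", "diabetes",
                   "race_ethnicity"),
    locations  = c("patient_id", "unit", "start_time", "end_time"),
    vitals     = c("patient_id", "time", "variable", "value"),
    labs       = c("patient_id", "time", "analyte", "value"),
    meds       = c("patient_id", "time", "is_antibiotic", "route"),
    cultures   = c("patient_id", "order_time")
  )
}

read_csv_quiet <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, show_col_types = FALSE)
}

#' Read a longitudinal cohort from CSV files
#'
#' Reads the six long-format event tables (`encounters.csv`, `locations.csv`,
#' `vitals.csv`, `labs.csv`, `meds.csv`, `cultures.csv`) from a directory (or
#' a named vector of paths), parses timestamps, coerces vocabulary columns,
#' and applies plausibility bounds to vital and lab values. Malformed rows are
#' collected in a rejects report, never silently dropped.
#'
#' @param paths Directory containing the standard file names, or a named
#'   character vector mapping table names to file paths.
#' @param bounds Plausibility bounds table, see [default_bounds()].
#' @return An `ews_cohort`: a list of typed, time-sorted tibbles
#'   (`encounters`, `locations`, `vitals`, `labs`, `meds`, `cultures`) plus a
#'   `rejects` tibble with one row per rejected input row and its reason.
#' @export
read_cohort <- function(paths, bounds = default_bounds()) {
  if (length(paths) == 1 && is.null(names(paths)) && dir.exists(paths)) {
    paths <- setNames(file.path(paths, cohort_file_names()),
                      names(cohort_file_names()))
  }
  req <- required_columns()
  missing_files <- setdiff(names(req), names(paths))
  if (length(missing_files) > 0) {
    stop("missing cohort tables: ", paste(missing_files, collapse = ", "))
  }
  raw <- lapply(names(req), function(tab) {
    path <- paths[[tab]]
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read_csv_quiet(path)
    missing_cols <- setdiff(req[[tab]], names(df))
    # death_time/bmi optional in the file; synthesize empty columns
    optional <- intersect(missing_cols, c("death_time", "bmi"))
    for (col in optional) df[[col]] <- NA_character_
    missing_cols <- setdiff(missing_cols, optional)
    if (length(missing_cols) > 0) {
      stop(sprintf("file '%s' is missing required column(s): %s",
                   path, paste(missing_cols, collapse = ", ")))
    }
    df
  })
  names(raw) <- names(req)

  rejects <- list()
  note_rejects <- function(df, bad, table, reason) {
    if (!any(bad)) return(NULL)
    tibble(table = table,
           patient_id = df$patient_id[bad],
           row = which(bad),
           reason = reason)
  }

  # encounters -----------------------------------------------------------
  enc <- raw$encounters
  enc_t <- tibble(
    patient_id = enc$patient_id,
    admit_time = parse_time(enc$admit_time),
    discharge_time = parse_time(enc$discharge_time),
    death_time = parse_time(enc$death_time),
    age_years = suppressWarnings(as.numeric(enc$age_years)),
    bmi = suppressWarnings(as.numeric(enc$bmi)),
    hypertensive_disorder = tolower(enc$hypertensive_disorder) %in% c("true", "1", "t", "yes"),
    diabetes = tolower(enc$diabetes) %in% c("true", "1", "t", "yes"),
    race_ethnicity = enc$race_ethnicity
  )
  bad <- is.na(enc_t$admit_time) | is.na(enc_t$discharge_time)
  rejects <- c(rejects, list(note_rejects(enc, bad, "encounters", "unparseable_timestamp")))
  enc_t <- enc_t[!bad, , drop = FALSE] |> arrange(.data$admit_time, .data$patient_id)

  # locations -------------------------------------------------------------
  loc <- raw$locations
  loc_t <- tibble(
    patient_id = loc$patient_id,
    unit = toupper(loc$unit),
    start_time = parse_time(loc$start_time),
    end_time = parse_time(loc$end_time)
  )
  bad_time <- is.na(loc_t$start_time) | is.na(loc_t$end_time)
  bad_unit <- !bad_time & !(loc_t$unit %in% UNIT_LEVELS)
  rejects <- c(rejects,
               list(note_rejects(loc, bad_time, "locations", "unparseable_timestamp")),
               list(note_rejects(loc, bad_unit, "locations", "unknown_unit")))
  loc_t <- loc_t[!(bad_time | bad_unit), , drop = FALSE] |>
    arrange(.data$patient_id, .data$start_time)

  # long value streams -----------------------------------------------------
  parse_stream <- function(df, var_col, vocab, table) {
    t <- parse_time(df$time)
    variable <- toupper(df[[var_col]])
    value_chr <- df$value
    value <- suppressWarnings(as.numeric(value_chr))
    # categorical recodings
    if (table == "vitals") {
      is_avpu <- variable == "AVPU" & toupper(value_chr) %in% names(AVPU_LEVELS)
      value[is_avpu] <- AVPU_LEVELS[toupper(value_chr[is_avpu])]
      is_bool <- variable == "SUPP_O2" & tolower(value_chr) %in% c("true", "false", "t", "f")
      value[is_bool] <- as.numeric(tolower(value_chr[is_bool]) %in% c("true", "t"))
    }
    bad_time <- is.na(t)
    bad_var <- !bad_time & !(variable %in% vocab)
    bad_val <- !bad_time & !bad_var & (is.na(value) | !is.finite(value))
    b <- bounds[match(variable, bounds$variable), ]
    oob <- !bad_time & !bad_var & !bad_val &
      (value < b$lower | value > b$upper)
    oob[is.na(oob)] <- FALSE
    rej <- bind_rows(
      note_rejects(df, bad_time, table, "unparseable_timestamp"),
      note_rejects(df, bad_var, table, "unknown_variable"),
      note_rejects(df, bad_val, table, "unparseable_value"),
      note_rejects(df, oob, table, "out_of_bounds")
    )
    keep <- !(bad_time | bad_var | bad_val | oob)
    out <- tibble(patient_id = df$patient_id[keep], time = t[keep],
                  variable = variable[keep], value = value[keep]) |>
      arrange(.data$patient_id, .data$time)
    list(data = out, rejects = rej)
  }

  vit <- parse_stream(raw$vitals, "variable", VITAL_VARIABLES, "vitals")
  lab <- parse_stream(
    raw$labs |> rename(variable = "analyte"), "variable", LAB_ANALYTES, "labs")
  lab$data <- lab$data |> rename(analyte = "variable")
  rejects <- c(rejects, list(vit$rejects), list(lab$rejects))

  # meds -------------------------------------------------------------------
  med <- raw$meds
  med_t <- tibble(
    patient_id = med$patient_id,
    time = parse_time(med$time),
    is_antibiotic = tolower(med$is_antibiotic) %in% c("true", "1", "t", "yes"),
    route = toupper(med$route)
  )
  bad <- is.na(med_t$time) | !(med_t$route %in% c("IV", "PO"))
  rejects <- c(rejects, list(note_rejects(med, bad, "meds", "unparseable_row")))
  med_t <- med_t[!bad, , drop = FALSE] |> arrange(.data$patient_id, .data$time)

  # cultures ---------------------------------------------------------------
  cul <- raw$cultures
  cul_t <- tibble(patient_id = cul$patient_id,
                  order_time = parse_time(cul$order_time))
  bad <- is.na(cul_t$order_time)
  rejects <- c(rejects, list(note_rejects(cul, bad, "cultures", "unparseable_timestamp")))
  cul_t <- cul_t[!bad, , drop = FALSE] |> arrange(.data$patient_id, .data$order_time)

  rejects <- bind_rows(rejects)
  if (nrow(rejects) == 0) {
    rejects <- tibble(table = character(), patient_id = character(),
                      row = integer(), reason = character())
  }

  new_cohort(encounters = enc_t, locations = loc_t, vitals = vit$data,
             labs = lab$data, meds = med_t, cultures = cul_t,
             rejects = rejects)
}

new_cohort <- function(encounters, locations, vitals, labs, meds, cultures,
                       rejects = NULL) {
  if (is.null(rejects)) {
    rejects <- tibble(table = character(), patient_id = character(),
                      row = integer(), reason = character())
  }
  structure(list(encounters = encounters, locations = locations,
                 vitals = vitals, labs = labs, meds = meds,
                 cultures = cultures, rejects = rejects),
            class = "ews_cohort")
}

#' @export
print.ews_cohort <- function(x, ...) {
  cat("<ews_cohort>\n")
  cat(sprintf("  %d encounters, %d location intervals\n",
              nrow(x$encounters), nrow(x$locations)))
  cat(sprintf("  %d vital events, %d lab events, %d med events, %d culture orders\n",
              nrow(x$vitals), nrow(x$labs), nrow(x$meds), nrow(x$cultures)))
  if (nrow(x$rejects) > 0) cat(sprintf("  %d rejected rows\n", nrow(x$rejects)))
  invisible(x)
}

#' Write a cohort back to CSV files
#'
#' Inverse of [read_cohort()]: writes the six event tables in canonical column
#' order with ISO-8601 minute-resolution timestamps. Reading the written files
#' back reproduces the accepted rows.
#'
#' @param cohort An `ews_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- setNames(file.path(dir, cohort_file_names()),
                    names(cohort_file_names()))
  fmt <- function(df) {
    for (col in names(df)) {
      if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_time(df[[col]])
    }
    df
  }
  enc <- fmt(cohort$encounters)
  vit <- cohort$vitals
  # AVPU / SUPP_O2 round-trip through their categorical encodings
  if (nrow(vit) > 0) {
    vit$value_out <- as.character(vit$value)
    is_avpu <- vit$variable == "AVPU"
    vit$value_out[is_avpu] <- names(AVPU_LEVELS)[vit$value[is_avpu] + 1]
    is_o2 <- vit$variable == "SUPP_O2"
    vit$value_out[is_o2] <- ifelse(vit$value[is_o2] > 0, "TRUE", "FALSE")
    vit <- vit |> select(-"value") |> rename(value = "value_out")
  }
  readr::write_csv(enc, paths["encounters"], progress = FALSE)
  readr::write_csv(fmt(cohort$locations), paths["locations"], progress = FALSE)
  readr::write_csv(fmt(vit), paths["vitals"], progress = FALSE)
  readr::write_csv(fmt(cohort$labs), paths["labs"], progress = FALSE)
  readr::write_csv(fmt(cohort$meds), paths["meds"], progress = FALSE)
  readr::write_csv(fmt(cohort$cultures), paths["cultures"], progress = FALSE)
  invisible(paths)
}

#' Check cohort structural invariants
#'
#' Report-only validation of the event-stream invariants: encounter ordering,
#' death within encounter, unique patient ids, location interval ordering,
#' non-overlap and containment, and events outside their encounter.
#'
#' @param cohort An `ews_cohort`.
#' @param strict If `TRUE`, any violation raises an error instead of being
#'   reported.
#' @return A tibble with columns `patient_id`, `rule`, `detail`; zero rows if
#'   the cohort is fully consistent.
#' @export
validate_cohort <- function(cohort, strict = FALSE) {
  enc <- cohort$encounters
  v <- list()
  add <- function(ids, rule, detail = "") {
    if (length(ids) == 0) return(NULL)
    tibble(patient_id = ids, rule = rule, detail = detail)
  }

  dup <- enc$patient_id[duplicated(enc$patient_id)]
  v <- c(v, list(add(unique(dup), "duplicate_patient_id")))

  bad <- enc$patient_id[enc$admit_time >= enc$discharge_time]
  v <- c(v, list(add(bad, "admit_not_before_discharge")))

  has_death <- !is.na(enc$death_time)
  bad <- enc$patient_id[has_death &
                          (enc$death_time < enc$admit_time |
                             enc$death_time > enc$discharge_time)]
  v <- c(v, list(add(bad, "death_outside_encounter")))

  loc <- cohort$locations
  bad <- loc$patient_id[loc$start_time >= loc$end_time]
  v <- c(v, list(add(unique(bad), "interval_nonpositive")))

  if (nrow(loc) > 0) {
    loc_o <- loc |> arrange(.data$patient_id, .data$start_time)
    ov <- loc_o |>
      group_by(.data$patient_id) |>
      mutate(overlap = .data$start_time <
               lag(.data$end_time,
                   default = as.POSIXct(-8e12, origin = "1970-01-01", tz = "UTC"))) |>
      ungroup()
    v <- c(v, list(add(unique(ov$patient_id[ov$overlap]), "interval_overlap")))

    j <- loc |> left_join(enc |> select("patient_id", "admit_time", "discharge_time"),
                          by = "patient_id")
    out <- is.na(j$admit_time) | j$start_time < j$admit_time |
      j$end_time > j$discharge_time
    v <- c(v, list(add(unique(j$patient_id[out]), "interval_outside_encounter")))
  }

  check_events <- function(df, time_col, table) {
    if (nrow(df) == 0) return(NULL)
    j <- df |> left_join(enc |> select("patient_id", "admit_time", "discharge_time"),
                         by = "patient_id")
    out <- is.na(j$admit_time) | j[[time_col]] < j$admit_time |
      j[[time_col]] > j$discharge_time
    add(unique(j$patient_id[out]), "event_outside_encounter", table)
  }
  v <- c(v, list(check_events(cohort$vitals, "time", "vitals")),
         list(check_events(cohort$labs, "time", "labs")),
         list(check_events(cohort$meds, "time", "meds")),
         list(check_events(cohort$cultures, "order_time", "cultures")))

  report <- bind_rows(v)
  if (nrow(report) == 0) {
    report <- tibble(patient_id = character(), rule = character(),
                     detail = character())
  }
  if (strict && nrow(report) > 0) {
    stop("cohort validation failed: ",
         paste(unique(report$rule), collapse = ", "))
  }
  report
}

#' LOCF carry-forward horizons
#'
#' How long a charted value remains usable when assembling observation
#' snapshots. Defaults: vitals 24 h, labs 48 h, mental status / supplemental
#' oxygen flags 24 h; carry-forward never crosses an encounter boundary.
#'
#' @param vitals_hours,labs_hours,status_hours Per-class staleness horizons in
#'   hours.
#' @return A named list of horizons in minutes, one entry per variable.
#' @export
locf_config <- function(vitals_hours = 24, labs_hours = 48, status_hours = 24) {
  stopifnot(vitals_hours >= 0, labs_hours >= 0, status_hours >= 0)
  h <- c(
    setNames(rep(vitals_hours * 60, 8),
             c("RR", "HR", "TEMP", "SBP", "DBP", "SPO2", "URINE_OUT", "FHR")),
    setNames(rep(status_hours * 60, 2), c("AVPU", "SUPP_O2")),
    setNames(rep(labs_hours * 60, length(LAB_ANALYTES)), LAB_ANALYTES)
  )
  as.list(h)
}

#' Assemble per-observation snapshots by last observation carried forward
#'
#' Emits one snapshot per distinct vital-charting time per patient while the
#' patient is located on the ward. Each variable slot carries the most recent
#' value whose age is within its staleness horizon; older or never-charted
#' slots are `NA`. Lab-only times do not create snapshots.
#'
#' @param cohort A validated `ews_cohort`.
#' @param locf Horizons from [locf_config()].
#' @return A tibble with one row per snapshot: `patient_id`, `time`,
#'   `in_scope_unit`, one column per variable, and one `<variable>_age_min`
#'   column giving the age of the carried value in minutes.
#' @export
assemble_snapshots <- function(cohort, locf = locf_config()) {
  all_vars <- c(VITAL_VARIABLES, LAB_ANALYTES)
  events <- bind_rows(
    cohort$vitals,
    cohort$labs |> rename(variable = "analyte")
  )
  empty <- function() {
    out <- tibble(patient_id = character(), time = as.POSIXct(character(), tz = "UTC"),
                  in_scope_unit = character())
    for (var in all_vars) {
      out[[var]] <- numeric()
      out[[paste0(var, "_age_min")]] <- numeric()
    }
    out
  }
  ward <- cohort$locations |> filter(.data$unit == "WARD")
  if (nrow(events) == 0 || nrow(ward) == 0) return(empty())

  ev_by_pat <- split(events, events$patient_id)
  ward_by_pat <- split(ward, ward$patient_id)
  pats <- intersect(names(ev_by_pat), names(ward_by_pat))

  rows <- lapply(pats, function(pid) {
    ev <- ev_by_pat[[pid]]
    w <- ward_by_pat[[pid]]
    vt <- ev$time[ev$variable %in% VITAL_VARIABLES]
    if (length(vt) == 0) return(NULL)
    on_ward <- rep(FALSE, length(vt))
    for (k in seq_len(nrow(w))) {
      on_ward <- on_ward | (vt >= w$start_time[k] & vt < w$end_time[k])
    }
    snap_times <- sort(unique(vt[on_ward]))
    if (length(snap_times) == 0) return(NULL)
    ns <- length(snap_times)
    cols <- vector("list", 3 + 2 * length(all_vars))
    names(cols) <- c("patient_id", "time", "in_scope_unit",
                     rbind(all_vars, paste0(all_vars, "_age_min")))
    cols[["patient_id"]] <- rep(pid, ns)
    cols[["time"]] <- snap_times
    cols[["in_scope_unit"]] <- rep("WARD", ns)
    snap_num <- as.numeric(snap_times)
    ev_num <- as.numeric(ev$time)
    for (var in all_vars) {
      sel <- ev$variable == var
      val <- rep(NA_real_, ns)
      age <- rep(NA_real_, ns)
      if (any(sel)) {
        et <- ev_num[sel]
        evv <- ev$value[sel]
        o <- order(et)
        et <- et[o]; evv <- evv[o]
        idx <- findInterval(snap_num, et)
        age_min <- (snap_num - et[pmax(idx, 1)]) / 60
        ok <- idx > 0 & age_min <= locf[[var]]
        val[ok] <- evv[idx[ok]]
        age[ok] <- age_min[ok]
      }
      cols[[var]] <- val
      cols[[paste0(var, "_age_min")]] <- age
    }
    tibble::new_tibble(cols, nrow = ns)
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0) return(empty())
  res |> arrange(.data$patient_id, .data$time)
}
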