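# Seeded synthetic obstetric ward cohort generator.
#
# Emulates the structure of the study data: encounters with demographics,
# ward/L&D/ICU location intervals, 4-hourly vital charting with obstetric
# baseline distributions, daily lab panels, and antibiotic/culture event
# streams. Deteriorators receive a linear pre-event physiologic drift;
# infected patients receive a fever/tachycardia drift plus an antibiotic
# course constructed to satisfy the infection phenotype. Per-patient RNG
# substreams are keyed by (seed, patient index) so adding patients never
# perturbs existing ones.

# Baseline vital/lab distributions anchored to obstetric ward medians/IQRs
# (no-outcome column). `dist` chooses the marginal family; sd is derived
# from the IQR (normal: width/1.349; lognormal: on the log scale).
baseline_table <- function() {
  tibble::tribble(
    ~variable,     ~median,  ~q1,   ~q3,   ~dist,
    "HR",            85,     75,    94,    "normal",
    "RR",            18,     18,    20,    "normal",
    "TEMP",          36.6,   36.3,  36.8,  "normal",
    "SBP",          117,    107,   129,    "normal",
    "DBP",           67,     60,    76,    "normal",
    "SPO2",          98,     97,    99,    "normal",
    "FHR",          140,    130,   150,    "normal",
    "WBC",           11.6,    9,    14.8,  "lognormal",
    "BUN",            8,      5,    11,    "lognormal",
    "CREATININE",     0.6,    0.5,   0.8,  "lognormal",
    "AST",           25,     17,    40,    "lognormal",
    "ALT",           20,     11,    48,    "lognormal",
    "HEMOGLOBIN",     9.8,    8.7,  10.8,  "normal",
    "PLATELETS",    203,    154,   259,    "lognormal",
  )
}

#' Synthetic cohort configuration
#'
#' All knobs of the generator with obstetric-ward defaults. Prevalences
#' default to the test-scale 5% (the package ships
#' [paper_scale_sim_config()] with the study-scale 0.2% / 0.4% rates for
#' long runs). The drift model shifts each listed vital linearly over the
#' final `drift_hours` before the event.
#'
#' @param n_patients Number of encounters to simulate.
#' @param deterioration_prevalence,infection_prevalence Per-patient event
#'   probabilities in `[0, 1]`.
#' @param charting_interval_hours,charting_jitter_hours Vital charting
#'   cadence and uniform jitter.
#' @param drift Named vector of per-variable shifts reached at the event
#'   time (defaults HR +25, RR +8, SBP -20, TEMP +1.2).
#' @param infection_drift Named vector for the infection course (fever and
#'   tachycardia).
#' @param drift_hours Ramp length in hours.
#' @param drift_scale Multiplier applied to both drift vectors (0 disables).
#' @param los_median_days,los_iqr_days Length-of-stay lognormal anchors for
#'   non-event patients; `event_los_median_days`, `event_los_iqr_days`
#'   likewise for event patients.
#' @param chain_mix Probabilities of the deterioration transfer chains
#'   `direct` (ward to ICU), `via_lnd` (qualifying, L&D dwell under 24 h),
#'   `nonqualifying` (L&D dwell over 24 h), `death` (death on the ward).
#' @param decoy_fraction Fraction of non-infected patients given antibiotic
#'   or culture decoys that must not satisfy the infection rule.
#' @param fhr_fraction Fraction of (antepartum) patients with fetal heart
#'   rate charting.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 200,
                       deterioration_prevalence = 0.05,
                       infection_prevalence = 0.05,
                       charting_interval_hours = 4,
                       charting_jitter_hours = 1,
                       drift = c(HR = 25, RR = 8, SBP = -20, TEMP = 1.2),
                       infection_drift = c(HR = 15, TEMP = 1.3),
                       drift_hours = 12,
                       drift_scale = 1,
                       los_median_days = 3, los_iqr_days = c(2, 3),
                       event_los_median_days = 8, event_los_iqr_days = c(6, 12),
                       chain_mix = c(direct = 0.6, via_lnd = 0.25,
                                     nonqualifying = 0.1, death = 0.05),
                       decoy_fraction = 0.05,
                       fhr_fraction = 0.3,
                       seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  stopifnot(n_patients >= 0,
            deterioration_prevalence >= 0, deterioration_prevalence <= 1,
            infection_prevalence >= 0, infection_prevalence <= 1,
            drift_hours > 0, drift_scale >= 0,
            abs(sum(chain_mix) - 1) < 1e-8)
  structure(list(
    n_patients = as.integer(n_patients),
    deterioration_prevalence = deterioration_prevalence,
    infection_prevalence = infection_prevalence,
    charting_interval_hours = charting_interval_hours,
    charting_jitter_hours = charting_jitter_hours,
    drift = drift, infection_drift = infection_drift,
    drift_hours = drift_hours, drift_scale = drift_scale,
    los_median_days = los_median_days, los_iqr_days = los_iqr_days,
    event_los_median_days = event_los_median_days,
    event_los_iqr_days = event_los_iqr_days,
    chain_mix = chain_mix, decoy_fraction = decoy_fraction,
    fhr_fraction = fhr_fraction,
    baselines = baseline_table(),
    bounds = index_bounds(default_bounds()),
    seed = as.integer(seed)), class = "sim_config")
}

#' Study-scale configuration
#'
#' Same generator with the study's event rates (deterioration 0.2%,
#' infection 0.4%) for large-n runs.
#' @param n_patients Number of encounters (default 19611).
#' @param seed Integer seed.
#' @param ... Further overrides passed to [sim_config()].
#' @export
paper_scale_sim_config <- function(n_patients = 19611, seed = NULL, ...) {
  sim_config(n_patients = n_patients, deterioration_prevalence = 0.002,
             infection_prevalence = 0.004, seed = seed, ...)
}

# minimal-overhead tibble constructor for the per-patient hot path
fast_tbl <- function(...) {
  l <- list(...)
  n <- max(vapply(l, length, 1L))
  l <- lapply(l, function(x) if (length(x) == n) x else rep(x, length.out = n))
  tibble::new_tibble(l, nrow = n)
}

# deterministic 32-bit substream seed from (seed, patient index)
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 9973) %% 2147483587) + 1L
}

iqr_sd <- function(q1, q3) (q3 - q1) / 1.349

draw_baseline <- function(bl, between_frac = 0.6) {
  # one per-patient baseline per variable; between-patient share of the
  # marginal sd is between_frac, the rest is within-patient noise
  vals <- numeric(nrow(bl))
  for (i in seq_len(nrow(bl))) {
    if (bl$dist[i] == "lognormal") {
      sdlog <- iqr_sd(log(bl$q1[i]), log(bl$q3[i]))
      vals[i] <- exp(rnorm(1, log(bl$median[i]), between_frac * sdlog))
    } else {
      s <- iqr_sd(bl$q1[i], bl$q3[i])
      vals[i] <- rnorm(1, bl$median[i], between_frac * s)
    }
  }
  setNames(vals, bl$variable)
}

within_sd <- function(bl, within_frac = 0.8) {
  s <- numeric(nrow(bl))
  for (i in seq_len(nrow(bl))) {
    s[i] <- if (bl$dist[i] == "lognormal") {
      # approximate on the natural scale at the median
      bl$median[i] * within_frac * iqr_sd(log(bl$q1[i]), log(bl$q3[i]))
    } else {
      within_frac * iqr_sd(bl$q1[i], bl$q3[i])
    }
  }
  setNames(s, bl$variable)
}

rlos_days <- function(median_days, iqr) {
  sdlog <- max(iqr_sd(log(iqr[1]), log(iqr[2])), 0.05)
  exp(rnorm(1, log(median_days), sdlog))
}

clip_bounds <- function(value, variable, bounds) {
  lo <- attr(bounds, "lo"); hi <- attr(bounds, "hi")
  if (is.null(lo)) {
    i <- match(variable, bounds$variable)
    return(pmin(pmax(value, bounds$lower[i]), bounds$upper[i]))
  }
  pmin(pmax(value, lo[[variable]]), hi[[variable]])
}

index_bounds <- function(bounds) {
  attr(bounds, "lo") <- setNames(bounds$lower, bounds$variable)
  attr(bounds, "hi") <- setNames(bounds$upper, bounds$variable)
  bounds
}

#' Simulate one synthetic cohort
#'
#' Generates every event table of the data model plus the ground truth.
#' Output is byte-identical under identical config and seed.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (an `ews_cohort`) and `ground_truth` (tibble
#'   with per-patient flags, chain types, and true event times).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  t0 <- as.POSIXct("2015-01-01 08:00", tz = "UTC")

  enc_rows <- vector("list", n); loc_rows <- vector("list", n)
  vit_rows <- vector("list", n); lab_rows <- vector("list", n)
  med_rows <- vector("list", n); cul_rows <- vector("list", n)
  gt_rows <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i))
    p <- simulate_patient(i, t0 + (i - 1) * 1800, config)
    enc_rows[[i]] <- p$encounter; loc_rows[[i]] <- p$locations
    vit_rows[[i]] <- p$vitals; lab_rows[[i]] <- p$labs
    med_rows[[i]] <- p$meds; cul_rows[[i]] <- p$cultures
    gt_rows[[i]] <- p$truth
  }

  empty_enc <- tibble(patient_id = character(),
                      admit_time = as.POSIXct(character(), tz = "UTC"),
                      discharge_time = as.POSIXct(character(), tz = "UTC"),
                      death_time = as.POSIXct(character(), tz = "UTC"),
                      age_years = numeric(), bmi = numeric(),
                      hypertensive_disorder = logical(), diabetes = logical(),
                      race_ethnicity = character())
  empty_ev <- function(cols) {
    out <- tibble(patient_id = character())
    for (cl in names(cols)) out[[cl]] <- cols[[cl]]
    out
  }
  cohort <- new_cohort(
    encounters = bind_rows(c(list(empty_enc), enc_rows)),
    locations = bind_rows(c(list(empty_ev(list(
      unit = character(), start_time = as.POSIXct(character(), tz = "UTC"),
      end_time = as.POSIXct(character(), tz = "UTC")))), loc_rows)),
    vitals = bind_rows(c(list(empty_ev(list(
      time = as.POSIXct(character(), tz = "UTC"), variable = character(),
      value = numeric()))), vit_rows)),
    labs = bind_rows(c(list(empty_ev(list(
      time = as.POSIXct(character(), tz = "UTC"), analyte = character(),
      value = numeric()))), lab_rows)),
    meds = bind_rows(c(list(empty_ev(list(
      time = as.POSIXct(character(), tz = "UTC"), is_antibiotic = logical(),
      route = character()))), med_rows)),
    cultures = bind_rows(c(list(empty_ev(list(
      order_time = as.POSIXct(character(), tz = "UTC")))), cul_rows))
  )
  gt <- bind_rows(gt_rows)
  if (nrow(gt) == 0) {
    gt <- tibble(patient_id = character(), is_deteriorator = logical(),
                 chain_type = character(), qualifying = logical(),
                 deterioration_time = as.POSIXct(character(), tz = "UTC"),
                 is_infected = logical(),
                 infection_time = as.POSIXct(character(), tz = "UTC"),
                 decoy = character(), drift_scale = numeric())
  }
  list(cohort = cohort, ground_truth = gt)
}

simulate_patient <- function(i, admit, config) {
  pid <- sprintf("P%05d", i)
  is_det <- runif(1) < config$deterioration_prevalence
  is_inf <- !is_det && runif(1) < config$infection_prevalence

  # encounter-level covariates; event patients more often hypertensive /
  # diabetic and with longer stays, mirroring the cohort-table contrasts
  age <- round(rnorm(1, 28, 6))
  age <- min(max(age, 18), 48)
  bmi <- round(rnorm(1, 31.5, 6.5), 1)
  htn <- runif(1) < if (is_det) 0.28 else 0.056
  dm <- runif(1) < if (is_det) 0.09 else 0.021
  race <- sample(c("Black", "White", "Hispanic", "Other"), 1,
                 prob = c(0.745, 0.116, 0.068, 0.071))

  los_d <- if (is_det || is_inf) {
    rlos_days(config$event_los_median_days, config$event_los_iqr_days)
  } else {
    rlos_days(config$los_median_days, config$los_iqr_days)
  }
  los_d <- max(los_d, 1.5)
  discharge <- admit + los_d * 86400

  chain <- if (is_det) {
    sample(names(config$chain_mix), 1, prob = config$chain_mix)
  } else "none"

  # location intervals and the true deterioration event time
  death_time <- as.POSIXct(NA)
  det_time <- as.POSIXct(NA)
  qualifying <- NA
  if (is_det) {
    # event somewhere in the middle-to-late stay, leaving room for the ramp
    frac <- runif(1, 0.5, 0.9)
    ward_end <- admit + max(frac * los_d * 86400, config$drift_hours * 3600 + 7200)
    if (ward_end >= discharge - 3600) ward_end <- discharge - 3600
    if (chain == "direct") {
      det_time <- ward_end
      qualifying <- TRUE
      loc <- fast_tbl(patient_id = pid, unit = c("WARD", "ICU"),
                    start_time = c(admit, ward_end),
                    end_time = c(ward_end, discharge))
    } else if (chain == "via_lnd") {
      dwell <- runif(1, 2, 12) * 3600
      icu_start <- ward_end + dwell
      if (icu_start >= discharge - 1800) icu_start <- discharge - 1800
      det_time <- icu_start
      qualifying <- TRUE
      loc <- fast_tbl(patient_id = pid, unit = c("WARD", "LND", "ICU"),
                    start_time = c(admit, ward_end, icu_start),
                    end_time = c(ward_end, icu_start, discharge))
    } else if (chain == "nonqualifying") {
      dwell <- runif(1, 26, 40) * 3600
      icu_start <- ward_end + dwell
      if (icu_start > discharge - 1800) discharge <- icu_start + 12 * 3600
      det_time <- ward_end
      qualifying <- FALSE
      loc <- fast_tbl(patient_id = pid, unit = c("WARD", "LND", "ICU"),
                    start_time = c(admit, ward_end, icu_start),
                    end_time = c(ward_end, icu_start, discharge))
    } else { # death on the ward
      death_time <- ward_end
      det_time <- ward_end
      discharge <- ward_end
      qualifying <- TRUE
      loc <- fast_tbl(patient_id = pid, unit = "WARD",
                    start_time = admit, end_time = ward_end)
    }
  } else {
    loc <- fast_tbl(patient_id = pid, unit = "WARD",
                  start_time = admit, end_time = discharge)
  }
  ward_end <- loc$end_time[loc$unit == "WARD"][1]

  # infection course: culture order mid-stay, IV antibiotics the same day,
  # IV/PO continuation through min(d0+3, discharge day - 1)
  inf_time <- as.POSIXct(NA)
  meds <- tibble(patient_id = character(),
                 time = as.POSIXct(character(), tz = "UTC"),
                 is_antibiotic = logical(), route = character())
  cultures <- tibble(patient_id = character(),
                     order_time = as.POSIXct(character(), tz = "UTC"))
  decoy <- "none"
  if (is_inf) {
    inf_time <- admit + runif(1, 0.25, 0.5) * los_d * 86400
    cultures <- fast_tbl(patient_id = pid, order_time = inf_time)
    d_cult <- cal_day(inf_time)
    d_dis <- cal_day(discharge)
    abx_days <- seq(d_cult, min(d_cult + 3, max(d_dis - 1, d_cult)))
    abx_t <- as.POSIXct(abx_days * 86400 + 10 * 3600,
                        origin = "1970-01-01", tz = "UTC")
    abx_t <- pmax(abx_t, admit + 60)
    abx_t <- pmin(abx_t, discharge - 60)
    meds <- fast_tbl(patient_id = pid, time = abx_t, is_antibiotic = TRUE,
                   route = c("IV", rep("PO", length(abx_t) - 1)))
  } else if (runif(1) < config$decoy_fraction) {
    decoy <- sample(c("short_abx", "late_iv", "culture_only"), 1)
    mid <- admit + 0.4 * los_d * 86400
    if (decoy == "short_abx") {
      meds <- fast_tbl(patient_id = pid, time = c(mid, mid + 86400),
                     is_antibiotic = TRUE, route = "IV")
    } else if (decoy == "late_iv") {
      cultures <- fast_tbl(patient_id = pid, order_time = mid)
      iv_t <- min(mid + 3 * 86400, discharge - 60)
      meds <- fast_tbl(patient_id = pid, time = iv_t,
                     is_antibiotic = TRUE, route = "IV")
    } else {
      cultures <- fast_tbl(patient_id = pid, order_time = mid)
    }
  }

  traj <- simulate_trajectory(pid, admit, ward_end, config,
                              det_time = if (is_det) det_time else NULL,
                              inf_time = if (is_inf) inf_time else NULL)

  enc <- fast_tbl(patient_id = pid, admit_time = admit,
                discharge_time = discharge, death_time = death_time,
                age_years = age, bmi = bmi, hypertensive_disorder = htn,
                diabetes = dm, race_ethnicity = race)
  truth <- fast_tbl(patient_id = pid, is_deteriorator = is_det,
                  chain_type = chain, qualifying = qualifying,
                  deterioration_time = det_time, is_infected = is_inf,
                  infection_time = inf_time, decoy = decoy,
                  drift_scale = config$drift_scale)
  list(encounter = enc, locations = loc, vitals = traj$vitals,
       labs = traj$labs, meds = meds, cultures = cultures, truth = truth)
}

#' Simulate one patient's vital and lab trajectory
#'
#' Baselines are drawn from the configured obstetric distributions; event
#' patients get the configured linear drift ramped over the final
#' `drift_hours` before their event time (infection drift plateaus for 24 h
#' after the culture). Values are clipped to the plausibility bounds.
#'
#' @param pid Patient id.
#' @param admit,ward_end Charting window (ward stay).
#' @param config A [sim_config()].
#' @param det_time,inf_time Event times (or `NULL`).
#' @return List with `vitals` and `labs` event tibbles.
#' @export
simulate_trajectory <- function(pid, admit, ward_end, config,
                                det_time = NULL, inf_time = NULL) {
  bl <- config$baselines
  base <- draw_baseline(bl)
  wsd <- within_sd(bl)
  step_h <- config$charting_interval_hours
  jit_h <- config$charting_jitter_hours

  dur_h <- as.numeric(difftime(ward_end, admit, units = "hours"))
  k <- max(1, floor((dur_h - 0.5) / step_h) + 1)
  times <- admit + (0.5 + (seq_len(k) - 1) * step_h +
                      runif(k, -jit_h, jit_h) * (seq_len(k) > 1)) * 3600
  times <- sort(pmin(pmax(times, admit + 60), ward_end - 60))
  times <- unique(times)

  ramp <- rep(0, length(times))
  drift <- config$drift * config$drift_scale
  if (!is.null(det_time)) {
    dt_h <- as.numeric(difftime(det_time, times, units = "hours"))
    ramp <- pmax(0, 1 - pmax(dt_h, 0) / config$drift_hours) * (dt_h >= 0)
  } else if (!is.null(inf_time)) {
    drift <- config$infection_drift * config$drift_scale
    dt_h <- as.numeric(difftime(inf_time, times, units = "hours"))
    up <- pmax(0, 1 - pmax(dt_h, 0) / config$drift_hours) * (dt_h >= 0)
    plateau <- (dt_h < 0) & (-dt_h <= 24)
    ramp <- pmax(up, as.numeric(plateau))
  }

  v_time <- list(); v_var <- list(); v_val <- list()
  core <- c("RR", "HR", "TEMP", "SBP", "DBP", "SPO2")
  for (var in core) {
    val <- base[[var]] + rnorm(length(times), 0, wsd[[var]])
    if (var %in% names(drift)) val <- val + drift[[var]] * ramp
    digits <- if (var == "TEMP") 1 else 0
    v_time[[var]] <- times
    v_var[[var]] <- rep(var, length(times))
    v_val[[var]] <- round(clip_bounds(val, var, config$bounds), digits)
  }
  # consciousness and supplemental oxygen: alert/off at baseline, possibly
  # abnormal close to a deterioration event
  avpu <- rep(0, length(times))
  o2 <- rep(0, length(times))
  if (!is.null(det_time)) {
    # part of the drift model: no drift, no pre-event status changes
    late <- ramp > 0.7
    p_flip <- 0.3 * min(1, config$drift_scale)
    avpu[late] <- rbinom(sum(late), 1, p_flip)
    o2[late] <- rbinom(sum(late), 1, p_flip)
  }
  v_time[["AVPU"]] <- times; v_var[["AVPU"]] <- rep("AVPU", length(times))
  v_val[["AVPU"]] <- avpu
  v_time[["SUPP_O2"]] <- times
  v_var[["SUPP_O2"]] <- rep("SUPP_O2", length(times))
  v_val[["SUPP_O2"]] <- o2
  # urine charted 12-hourly; unquantified urine recorded as 0
  u_idx <- seq(1, length(times), by = max(1, round(12 / step_h)))
  u_val <- ifelse(runif(length(u_idx)) < 0.5, 0,
                  round(exp(rnorm(length(u_idx), log(850), 0.5))))
  v_time[["URINE_OUT"]] <- times[u_idx]
  v_var[["URINE_OUT"]] <- rep("URINE_OUT", length(u_idx))
  v_val[["URINE_OUT"]] <- clip_bounds(u_val, "URINE_OUT", config$bounds)
  if (runif(1) < config$fhr_fraction) {
    fhr <- round(clip_bounds(base[["FHR"]] + rnorm(length(times), 0, wsd[["FHR"]]),
                             "FHR", config$bounds))
    v_time[["FHR"]] <- times; v_var[["FHR"]] <- rep("FHR", length(times))
    v_val[["FHR"]] <- fhr
  }
  vt <- do.call(c, unname(v_time))
  vv <- do.call(c, unname(v_var))
  vx <- do.call(c, unname(v_val))
  o <- order(vt, vv)
  vitals <- fast_tbl(patient_id = pid, time = vt[o], variable = vv[o],
                   value = vx[o])

  # daily lab panel at 06:00-ish
  lab_days <- unique(cal_day(times))
  lab_t <- as.POSIXct(lab_days * 86400 + 6 * 3600,
                      origin = "1970-01-01", tz = "UTC")
  lab_t <- lab_t[lab_t >= admit & lab_t <= ward_end]
  labs <- tibble(patient_id = character(),
                 time = as.POSIXct(character(), tz = "UTC"),
                 analyte = character(), value = numeric())
  if (length(lab_t) > 0) {
    l_val <- lapply(LAB_ANALYTES, function(var) {
      val <- base[[var]] + rnorm(length(lab_t), 0, wsd[[var]])
      if (var == "WBC" && (!is.null(det_time) || !is.null(inf_time))) {
        ev_t <- if (!is.null(det_time)) det_time else inf_time
        dt_h <- as.numeric(difftime(ev_t, lab_t, units = "hours"))
        r <- pmax(0, 1 - pmax(dt_h, 0) / 24) * (dt_h >= -24)
        val <- val * (1 + 0.4 * config$drift_scale * r)
      }
      clip_bounds(round(pmax(val, 0.01), 2), var, config$bounds)
    })
    lt <- rep(lab_t, length(LAB_ANALYTES))
    la <- rep(LAB_ANALYTES, each = length(lab_t))
    lx <- do.call(c, l_val)
    o <- order(lt, la)
    labs <- fast_tbl(patient_id = pid, time = lt[o], analyte = la[o],
                   value = lx[o])
  }
  list(vitals = vitals, labs = labs)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> n=%d, deterioration %.3f, infection %.3f, ",
                     "drift x%.1f over %g h, seed %d\n"),
              x$n_patients, x$deterioration_prevalence,
              x$infection_prevalence, x$drift_scale, x$drift_hours, x$seed))
  invisible(x)
}

#' Write ground truth alongside the cohort CSVs
#' @param ground_truth Tibble from [simulate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the file path.
#' @export
write_ground_truth <- function(ground_truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "ground_truth.csv")
  gt <- ground_truth
  for (col in names(gt)) {
    if (inherits(gt[[col]], "POSIXct")) gt[[col]] <- format_time(gt[[col]])
  }
  readr::write_csv(gt, path, progress = FALSE)
  invisible(path)
}
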