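# Scoring engine: vectorized band lookup over snapshot tables, plus the
# per-system wrappers and the pluggable continuous risk-model interface.

# Mean arterial pressure, derived when both pressures are present.
derive_map <- function(sbp, dbp) (sbp + 2 * dbp) / 3

snapshot_matrix <- function(snapshots, variables) {
  out <- list()
  for (var in variables) {
    if (var == "MAP") {
      sbp <- snapshots[["SBP"]] %||% rep(NA_real_, nrow(snapshots))
      dbp <- snapshots[["DBP"]] %||% rep(NA_real_, nrow(snapshots))
      out[[var]] <- derive_map(sbp, dbp)
    } else {
      out[[var]] <- snapshots[[var]] %||% rep(NA_real_, nrow(snapshots))
    }
  }
  out
}

#' Score snapshots against one system configuration
#'
#' Vectorized band lookup: each present variable is matched against the
#' system's threshold bands; missing variables contribute nothing (they lower
#' `completeness` instead). Aggregate systems sum the matched point weights;
#' trigger systems ordinalize severity (yellow/non-severe = 1, red/severe =
#' 2, criterion = 1) and sum, so the published trigger rule is exactly
#' `ordinal >= trigger_threshold`.
#'
#' @param snapshots Snapshot tibble from [assemble_snapshots()] (or any tibble
#'   with `patient_id`, `time` and variable columns).
#' @param config An `ews_score_config`.
#' @param details If `TRUE`, attach a per-row list column `components` with
#'   the matched band and contribution per variable.
#' @return A tibble: `patient_id`, `time`, `system`, `ordinal_value`,
#'   `trigger`, `completeness` (fraction of system variables present), and
#'   optionally `components`.
#' @export
score_snapshots <- function(snapshots, config, details = FALSE) {
  n <- nrow(snapshots)
  vars <- unique(config$bands$variable)
  mat <- snapshot_matrix(snapshots, vars)
  ordinal <- integer(n)
  present <- integer(n)
  comp_rows <- if (details) vector("list", n) else NULL
  if (details) for (i in seq_len(n)) comp_rows[[i]] <- list()

  level_weight <- c(YELLOW = 1L, RED = 2L, NONSEVERE = 1L, SEVERE = 2L,
                    CRITERION = 1L)
  for (var in vars) {
    v <- mat[[var]]
    has <- !is.na(v)
    present <- present + as.integer(has)
    vb <- config$bands[config$bands$variable == var, ]
    contrib <- integer(n)
    matched_band <- rep(NA_integer_, n)
    for (b in seq_len(nrow(vb))) {
      band <- vb[b, ]
      hit <- has & band_allows(band, v)
      if (!any(hit)) next
      w <- if (config$rule == "SUM_POINTS") band$points else
        level_weight[[band$level]]
      contrib[hit] <- contrib[hit] + w
      matched_band[hit] <- b
    }
    ordinal <- ordinal + contrib
    if (details) {
      for (i in which(has)) {
        comp_rows[[i]][[var]] <- list(
          value = v[i],
          band = if (is.na(matched_band[i])) NA else
            paste0(if (vb$lower_closed[matched_band[i]]) "[" else "(",
                   vb$lower[matched_band[i]], ",", vb$upper[matched_band[i]],
                   if (vb$upper_closed[matched_band[i]]) "]" else ")"),
          contribution = contrib[i],
          level = if (is.na(matched_band[i])) NA_character_ else
            vb$level[matched_band[i]]
        )
      }
    }
  }

  out <- tibble(
    patient_id = snapshots[["patient_id"]] %||% rep(NA_character_, n),
    time = snapshots[["time"]] %||% rep(as.POSIXct(NA), n),
    system = config$system,
    ordinal_value = as.integer(ordinal),
    trigger = ordinal >= config$trigger_threshold,
    completeness = if (length(vars) > 0) present / length(vars) else 0
  )
  if (details) out$components <- comp_rows
  out
}

score_one <- function(snapshot, config) {
  score_snapshots(snapshot, config, details = TRUE)
}

#' Modified Early Warning Score (aggregate weighted)
#' @param snapshot One-row (or multi-row) snapshot tibble.
#' @param config Score configuration; defaults to the shipped MEWS bands.
#' @return A `ScoreResult` tibble row, see [score_snapshots()].
#' @export
score_mews <- function(snapshot, config = load_score_config("mews")) {
  stopifnot(config$rule == "SUM_POINTS")
  score_one(snapshot, config)
}

#' National Early Warning Score (aggregate weighted)
#' @inheritParams score_mews
#' @export
score_news <- function(snapshot, config = load_score_config("news")) {
  stopifnot(config$rule == "SUM_POINTS")
  score_one(snapshot, config)
}

#' Modified Early Obstetric Warning System (red/yellow trigger)
#'
#' Triggers on a single markedly abnormal observation (red) or two
#' simultaneous mildly abnormal observations (two yellows); the ordinal value
#' is `yellow + 2 * red`, so trigger is equivalent to ordinal >= 2.
#' @inheritParams score_mews
#' @export
score_meows <- function(snapshot, config = load_score_config("meows")) {
  stopifnot(config$rule == "RED_YELLOW")
  score_one(snapshot, config)
}

#' Maternal Early Warning Criteria (single-parameter trigger)
#'
#' Any single abnormal value beyond a criterion threshold triggers; the
#' ordinal value counts the criteria met.
#' @inheritParams score_mews
#' @export
score_mewc <- function(snapshot, config = load_score_config("mewc")) {
  stopifnot(config$rule == "ANY_CRITERION")
  score_one(snapshot, config)
}

#' Maternal Early Warning Trigger (severe/non-severe trigger)
#'
#' Triggers on one severe or two non-severe abnormalities; ordinal value is
#' `nonsevere + 2 * severe`. Mean arterial pressure is derived from SBP and
#' DBP when both are present. Subjective elements of the published tool
#' (nursing concern, symptoms) are not representable in EHR event streams and
#' are excluded.
#' @inheritParams score_mews
#' @export
score_mewt <- function(snapshot, config = load_score_config("mewt")) {
  stopifnot(config$rule == "SEVERE_NONSEVERE")
  score_one(snapshot, config)
}

#' Score snapshots with every configured system
#'
#' @param snapshots Snapshot tibble.
#' @param configs Named list of configurations (default: all five built-ins).
#' @param risk_model Optional fitted model from [fit_surrogate_risk_model()];
#'   adds rows with `system = "RISK_MODEL"` whose `ordinal_value` column is
#'   `NA` and whose `probability` column holds the predicted probability.
#' @return Long tibble, one row per snapshot x system.
#' @export
score_all <- function(snapshots, configs = default_score_configs(),
                      risk_model = NULL) {
  res <- bind_rows(lapply(configs, function(cfg) score_snapshots(snapshots, cfg)))
  res$probability <- NA_real_
  if (!is.null(risk_model) && nrow(snapshots) > 0) {
    p <- predict_risk(risk_model, snapshots)
    res <- bind_rows(res, tibble(
      patient_id = snapshots$patient_id, time = snapshots$time,
      system = "RISK_MODEL", ordinal_value = NA_integer_,
      trigger = NA, completeness = NA_real_, probability = p))
  }
  res |> arrange(.data$patient_id, .data$time, .data$system)
}

#' Require a trigger to persist across consecutive observations
#'
#' Optional post-filter for trigger systems whose published form requires a
#' sustained abnormality: a trigger is kept only if the previous observation
#' for the same patient, within `minutes`, also triggered. Off by default in
#' every pipeline.
#'
#' @param scores Long score table from [score_all()] or [score_snapshots()].
#' @param minutes Maximum spacing between the two consecutive triggering
#'   observations.
#' @return The score table with `trigger` filtered.
#' @export
apply_persistence_filter <- function(scores, minutes = 20) {
  scores |>
    group_by(.data$patient_id, .data$system) |>
    arrange(.data$time, .by_group = TRUE) |>
    mutate(trigger = .data$trigger &
             lag(.data$trigger, default = FALSE) &
             as.numeric(difftime(.data$time, lag(.data$time), units = "mins")) <= minutes) |>
    ungroup()
}

# ---- pluggable continuous risk model (surrogate for ML scores) ----------

RISK_MODEL_DEFAULT_VARS <- c("RR", "HR", "TEMP", "SBP", "DBP", "SPO2",
                             "WBC", "CREATININE", "HEMOGLOBIN", "PLATELETS")

#' Fit a surrogate continuous risk model
#'
#' Random-forest classifier over snapshot variables predicting the
#' observation-level outcome label; a stand-in implementation of the
#' continuous-score interface so that pipelines comparing rule-based scores
#' against a probabilistic model can run end to end. Missing values are
#' median-imputed from the training data (imputation values are stored with
#' the model).
#'
#' @param snapshots Snapshot tibble.
#' @param labels Binary 0/1 vector, one per snapshot row.
#' @param variables Predictor columns (defaults to core vitals + labs).
#' @param seed Integer seed; fitting is reproducible given the seed.
#' @param ntree,cv_folds Forest size and number of cross-validation folds for
#'   the training report.
#' @return An `ews_risk_model` with elements `forest`, `variables`, `impute`,
#'   `seed`, and `cv_auc` (cross-validated AUC on the training cohort).
#' @export
fit_surrogate_risk_model <- function(snapshots, labels,
                                     variables = RISK_MODEL_DEFAULT_VARS,
                                     seed = 1L, ntree = 200, cv_folds = 5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("degenerate_labels")
  variables <- intersect(variables, names(snapshots))
  x <- as.data.frame(snapshots[, variables, drop = FALSE])
  impute <- vapply(x, function(col) {
    m <- median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, numeric(1))
  for (v in variables) x[[v]][is.na(x[[v]])] <- impute[[v]]
  y <- factor(labels, levels = c(0, 1))

  set.seed(seed)
  forest <- randomForest::randomForest(x = x, y = y, ntree = ntree)

  # cross-validated AUC for the training report
  set.seed(seed + 1L)
  fold <- sample(rep_len(seq_len(cv_folds), length(y)))
  cv_pred <- rep(NA_real_, length(y))
  for (k in seq_len(cv_folds)) {
    tr <- fold != k
    if (length(unique(labels[tr])) < 2) next
    f <- randomForest::randomForest(x = x[tr, , drop = FALSE],
                                    y = y[tr], ntree = ntree)
    cv_pred[!tr] <- predict(f, x[!tr, , drop = FALSE], type = "prob")[, "1"]
  }
  ok <- !is.na(cv_pred)
  cv_auc <- if (sum(labels[ok]) > 0 && sum(1 - labels[ok]) > 0) {
    compute_auc(cv_pred[ok], labels[ok])$auc
  } else NA_real_

  structure(list(forest = forest, variables = variables, impute = impute,
                 seed = seed, cv_auc = cv_auc),
            class = "ews_risk_model")
}

#' Predict deterioration probability from a fitted risk model
#' @param model An `ews_risk_model`.
#' @param snapshots Snapshot tibble.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_risk <- function(model, snapshots) {
  x <- as.data.frame(snapshots[, model$variables, drop = FALSE])
  for (v in model$variables) x[[v]][is.na(x[[v]])] <- model$impute[[v]]
  as.numeric(predict(model$forest, x, type = "prob")[, "1"])
}

#' @export
print.ews_risk_model <- function(x, ...) {
  cat(sprintf("<ews_risk_model> random forest on %d variables, cv AUC %.3f\n",
              length(x$variables), x$cv_auc))
  invisible(x)
}
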