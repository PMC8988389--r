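# Observation-level, forward-looking evaluation.
#
# Each ward observation is labeled by whether the patient's first outcome
# event falls within the following `horizon` hours; AUCs use the midrank
# (ties = 1/2) estimator with DeLong structural-component variance, and
# paired score comparisons use the DeLong covariance z-test.

#' Label ward observations by outcome occurrence within a forward window
#'
#' The label is 1 iff the patient's first outcome event time lies in
#' `(t, t + horizon]`. Observations at or after the first event are excluded
#' (the count of exclusions is attached as attribute `n_excluded`).
#'
#' @param observations Tibble with `patient_id` and `time` (snapshots or a
#'   wide score table).
#' @param events Outcome events tibble (`patient_id`, `kind`, `event_time`).
#' @param kind Outcome kind to label against (`"DETERIORATION"` or
#'   `"INFECTION"`); `NULL` uses all kinds pooled.
#' @param horizon_hours Forward window length, must be positive (default 24).
#' @return `observations` with a `label` column (0/1), rows at/after the
#'   event removed; attributes `n_excluded` and `horizon_hours`.
#' @export
label_observations <- function(observations, events, kind = "DETERIORATION",
                               horizon_hours = 24) {
  if (horizon_hours <= 0) stop("horizon must be positive")
  if (!is.null(kind)) events <- events[events$kind %in% kind, , drop = FALSE]
  first_event <- events |>
    filter(!is.na(.data$event_time)) |>
    group_by(.data$patient_id) |>
    summarise(event_time = min(.data$event_time), .groups = "drop")
  obs <- observations |>
    left_join(first_event, by = "patient_id")
  dt_h <- as.numeric(difftime(obs$event_time, obs$time, units = "hours"))
  after <- !is.na(dt_h) & dt_h <= 0
  out <- obs[!after, , drop = FALSE]
  dt_h <- dt_h[!after]
  out$label <- as.integer(!is.na(dt_h) & dt_h <= horizon_hours)
  out$event_time <- NULL
  attr(out, "n_excluded") <- sum(after)
  attr(out, "horizon_hours") <- horizon_hours
  out
}

# DeLong structural components: theta (midrank AUC), per-positive V10 and
# per-negative V01 vectors.
delong_components <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("degenerate_labels")
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  theta <- sum(r_all[seq_len(m)] - r_pos) / (m * n)
  list(theta = theta, v10 = v10, v01 = v01, m = m, n = n)
}

var_or_zero <- function(x) if (length(x) > 1) var(x) else 0

#' AUC with DeLong variance
#'
#' Midrank (ties counted one-half) estimate of the probability that a random
#' positive observation outscores a random negative one, with the DeLong
#' nonparametric variance and a normal-approximation 95% CI truncated to
#' `[0, 1]`. Constant scores give AUC exactly 0.5 with zero variance.
#'
#' @param scores Numeric score vector.
#' @param labels Binary 0/1 vector of the same length.
#' @return List with `auc`, `variance`, `ci` (length-2), `n_pos`, `n_neg`.
#' @export
compute_auc <- function(scores, labels) {
  dc <- delong_components(scores, labels)
  v <- var_or_zero(dc$v10) / dc$m + var_or_zero(dc$v01) / dc$n
  half <- 1.96 * sqrt(v)
  list(auc = dc$theta, variance = v,
       ci = c(max(0, dc$theta - half), min(1, dc$theta + half)),
       n_pos = dc$m, n_neg = dc$n)
}

#' Paired DeLong test comparing two correlated AUCs
#'
#' Both score vectors must be aligned to the same labeled observations. The
#' variance of the AUC difference uses the DeLong covariance of the two
#' estimators; the two-sided p-value comes from the normal reference.
#' Comparing a score with itself gives difference 0 and p = 1 exactly.
#'
#' @param scores_a,scores_b Aligned numeric score vectors.
#' @param labels Shared binary labels.
#' @return List with `auc_a`, `auc_b`, `difference`, `se`, `z`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  a <- delong_components(scores_a, labels)
  b <- delong_components(scores_b, labels)
  cov_or_zero <- function(x, y) if (length(x) > 1) stats::cov(x, y) else 0
  s10 <- cov_or_zero(a$v10, a$v10); s01 <- cov_or_zero(a$v01, a$v01)
  t10 <- cov_or_zero(b$v10, b$v10); t01 <- cov_or_zero(b$v01, b$v01)
  c10 <- cov_or_zero(a$v10, b$v10); c01 <- cov_or_zero(a$v01, b$v01)
  v <- (s10 + t10 - 2 * c10) / a$m + (s01 + t01 - 2 * c01) / a$n
  d <- a$theta - b$theta
  if (v <= 0) {
    # zero variance of the difference: identical rankings
    return(list(auc_a = a$theta, auc_b = b$theta, difference = d, se = 0,
                z = if (d == 0) 0 else sign(d) * Inf,
                p_value = if (d == 0) 1 else 0))
  }
  z <- d / sqrt(v)
  list(auc_a = a$theta, auc_b = b$theta, difference = d, se = sqrt(v),
       z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Accuracy at score thresholds
#'
#' For each threshold the alert rule is `score >= threshold`. Exact confusion
#' counts, sensitivity, specificity, PPV and NPV are reported.
#'
#' @param scores,labels As in [compute_auc()].
#' @param thresholds Thresholds to tabulate; default all distinct score
#'   values.
#' @return Tibble with one row per threshold.
#' @export
threshold_metrics <- function(scores, labels, thresholds = NULL) {
  labels <- as.integer(labels)
  if (is.null(thresholds)) thresholds <- sort(unique(scores))
  rows <- lapply(thresholds, function(thr) {
    alert <- scores >= thr
    tp <- sum(alert & labels == 1); fp <- sum(alert & labels == 0)
    fn <- sum(!alert & labels == 1); tn <- sum(!alert & labels == 0)
    tibble(threshold = thr, tp = tp, fp = fp, tn = tn, fn = fn,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
           ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  })
  bind_rows(rows)
}

#' Efficiency (alarm-burden) curve
#'
#' One point per distinct threshold: the fraction of observations that would
#' alert (`score >= threshold`) against the sensitivity attained at that
#' threshold. Points are sorted by alert fraction; the lowest threshold
#' always yields the point (1, 1).
#'
#' @param scores,labels As in [compute_auc()].
#' @return Tibble with columns `threshold`, `alert_fraction`, `sensitivity`.
#' @export
efficiency_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  rows <- lapply(thresholds, function(thr) {
    alert <- scores >= thr
    tibble(threshold = thr,
           alert_fraction = mean(alert),
           sensitivity = if (n_pos > 0) sum(alert & labels == 1) / n_pos else NA_real_)
  })
  bind_rows(rows) |> arrange(.data$alert_fraction)
}

# round half away from zero, the convention of clinical tables
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

pct1 <- function(num, den) round_half_up(100 * num / den, 1)

#' Cohort characteristics summary by outcome group
#'
#' Builds a clinical "Table 1": per outcome group (any event vs none), n and
#' median (IQR) for continuous covariates, n (%) for categoricals, with
#' rank-sum or chi-squared group comparisons. Percentages are rounded to one
#' decimal, half away from zero.
#'
#' @param cohort An `ews_cohort`.
#' @param events Outcome events used to split the groups.
#' @param kind Outcome kind(s) defining the event group (default
#'   `"DETERIORATION"`).
#' @return Tibble with one row per covariate (or covariate level):
#'   `variable`, `level`, `type`, numeric group summaries (`*_outcome`,
#'   `*_no_outcome`), `pct_*` for categoricals, and `p_value`.
#' @export
summarize_cohort <- function(cohort, events, kind = "DETERIORATION") {
  enc <- cohort$encounters
  event_ids <- unique(events$patient_id[events$kind %in% kind])
  grp <- enc$patient_id %in% event_ids
  n1 <- sum(grp); n0 <- sum(!grp)
  enc$los_days <- as.numeric(difftime(enc$discharge_time, enc$admit_time,
                                      units = "days"))
  enc$mortality <- !is.na(enc$death_time)

  cont_row <- function(name, x) {
    q1 <- quantile(x[grp], c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    q0 <- quantile(x[!grp], c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    p <- if (n1 > 0 && n0 > 0 &&
             sum(!is.na(x[grp])) > 0 && sum(!is.na(x[!grp])) > 0) {
      suppressWarnings(stats::wilcox.test(x[grp], x[!grp])$p.value)
    } else NA_real_
    tibble(variable = name, level = NA_character_, type = "continuous",
           n_outcome = n1, n_no_outcome = n0,
           median_outcome = if (n1 > 0) q1[2] else NA_real_,
           q1_outcome = if (n1 > 0) q1[1] else NA_real_,
           q3_outcome = if (n1 > 0) q1[3] else NA_real_,
           median_no_outcome = q0[2], q1_no_outcome = q0[1],
           q3_no_outcome = q0[3],
           count_outcome = NA_integer_, count_no_outcome = NA_integer_,
           pct_outcome = NA_real_, pct_no_outcome = NA_real_,
           p_value = p)
  }
  cat_row <- function(name, flag, level = NA_character_) {
    c1 <- sum(flag & grp); c0 <- sum(flag & !grp)
    p <- if (n1 > 0 && n0 > 0) {
      tab <- table(factor(grp, c(FALSE, TRUE)), factor(flag, c(FALSE, TRUE)))
      suppressWarnings(stats::chisq.test(tab)$p.value)
    } else NA_real_
    tibble(variable = name, level = level, type = "categorical",
           n_outcome = n1, n_no_outcome = n0,
           median_outcome = NA_real_, q1_outcome = NA_real_,
           q3_outcome = NA_real_, median_no_outcome = NA_real_,
           q1_no_outcome = NA_real_, q3_no_outcome = NA_real_,
           count_outcome = c1, count_no_outcome = c0,
           pct_outcome = if (n1 > 0) pct1(c1, n1) else NA_real_,
           pct_no_outcome = if (n0 > 0) pct1(c0, n0) else NA_real_,
           p_value = p)
  }

  rows <- list(
    tibble(variable = "n", level = NA_character_, type = "count",
           n_outcome = n1, n_no_outcome = n0,
           median_outcome = NA_real_, q1_outcome = NA_real_,
           q3_outcome = NA_real_, median_no_outcome = NA_real_,
           q1_no_outcome = NA_real_, q3_no_outcome = NA_real_,
           count_outcome = n1, count_no_outcome = n0,
           pct_outcome = pct1(n1, n1 + n0),
           pct_no_outcome = pct1(n0, n1 + n0), p_value = NA_real_),
    cont_row("age_years", enc$age_years),
    cont_row("bmi", enc$bmi),
    cont_row("los_days", enc$los_days),
    cat_row("hypertensive_disorder", enc$hypertensive_disorder),
    cat_row("diabetes", enc$diabetes),
    cat_row("mortality", enc$mortality)
  )
  races <- sort(unique(enc$race_ethnicity))
  races <- races[!is.na(races)]
  for (r in races) {
    rows <- c(rows, list(cat_row("race_ethnicity", enc$race_ethnicity == r, r)))
  }
  bind_rows(rows)
}

#' Full comparison bundle across scoring systems
#'
#' Computes, for a labeled wide score table, the AUC (with DeLong CI) per
#' system, the symmetric pairwise DeLong p-value matrix, threshold accuracy
#' tables, and efficiency curves.
#'
#' @param labeled Tibble with a `label` column and one numeric score column
#'   per system.
#' @param systems Score column names (default: every numeric column except
#'   `label`).
#' @return List with tibbles `auc`, `delong` (long pairwise), `thresholds`,
#'   `efficiency`, and matrix `delong_p`.
#' @export
compare_all_systems <- function(labeled, systems = NULL) {
  if (is.null(systems)) {
    systems <- setdiff(names(labeled)[vapply(labeled, is.numeric, logical(1))],
                       c("label"))
  }
  if (length(systems) < 1) stop("no score columns to compare")
  labels <- labeled$label

  auc_tbl <- bind_rows(lapply(systems, function(s) {
    a <- compute_auc(labeled[[s]], labels)
    tibble(system = s, auc = a$auc, variance = a$variance,
           ci_lower = a$ci[1], ci_upper = a$ci[2],
           n_pos = a$n_pos, n_neg = a$n_neg)
  })) |> arrange(desc(.data$auc))

  pairs <- if (length(systems) >= 2) utils::combn(systems, 2, simplify = FALSE) else list()
  delong_tbl <- bind_rows(lapply(pairs, function(pr) {
    d <- delong_compare(labeled[[pr[1]]], labeled[[pr[2]]], labels)
    tibble(system_a = pr[1], system_b = pr[2], auc_a = d$auc_a,
           auc_b = d$auc_b, difference = d$difference, z = d$z,
           p_value = d$p_value)
  }))
  p_mat <- matrix(1, length(systems), length(systems),
                  dimnames = list(systems, systems))
  for (i in seq_len(nrow(delong_tbl))) {
    p_mat[delong_tbl$system_a[i], delong_tbl$system_b[i]] <- delong_tbl$p_value[i]
    p_mat[delong_tbl$system_b[i], delong_tbl$system_a[i]] <- delong_tbl$p_value[i]
  }

  thr_tbl <- bind_rows(lapply(systems, function(s) {
    threshold_metrics(labeled[[s]], labels) |> mutate(system = s, .before = 1)
  }))
  eff_tbl <- bind_rows(lapply(systems, function(s) {
    efficiency_curve(labeled[[s]], labels) |> mutate(system = s, .before = 1)
  }))

  list(auc = auc_tbl, delong = delong_tbl, delong_p = p_mat,
       thresholds = thr_tbl, efficiency = eff_tbl)
}

#' Pivot a long score table to one column per system, with labels
#'
#' Convenience bridge from [score_all()] output to [compare_all_systems()]:
#' spreads `ordinal_value` (or `probability` for a continuous model) to wide
#' columns and attaches forward-window labels.
#'
#' @param scores Long score table from [score_all()].
#' @param events Outcome events.
#' @param kind,horizon_hours Passed to [label_observations()].
#' @return Wide labeled tibble (`patient_id`, `time`, one column per system,
#'   `label`).
#' @export
labeled_score_matrix <- function(scores, events, kind = "DETERIORATION",
                                 horizon_hours = 24) {
  val <- ifelse(scores$system == "RISK_MODEL" & !is.na(scores$probability),
                scores$probability, as.numeric(scores$ordinal_value))
  wide <- scores |>
    mutate(value = val) |>
    select("patient_id", "time", "system", "value") |>
    tidyr::pivot_wider(names_from = "system", values_from = "value")
  label_observations(wide, events, kind = kind, horizon_hours = horizon_hours)
}
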