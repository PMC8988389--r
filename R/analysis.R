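# Simulation study helpers: drift-recovery and null-calibration analyses of
# the rule-based scores on synthetic cohorts. Used by the test suite and the
# repository's acceptance script; exported so users can rerun the same
# analyses at other problem sizes.

#' Observation-level AUCs of the rule-based scores on one synthetic cohort
#'
#' Simulates a cohort, assembles ward snapshots, phenotypes outcomes, scores
#' every system, labels with the 24 h forward window, and returns the AUC
#' table.
#'
#' @param config A [sim_config()].
#' @param systems Score systems to evaluate.
#' @param kind Outcome kind to label against.
#' @return Tibble from [compare_all_systems()]'s `auc` element with the
#'   simulation seed and drift scale attached.
#' @export
simulated_cohort_aucs <- function(config, systems = SCORE_SYSTEMS,
                                  kind = "DETERIORATION") {
  sim <- simulate_cohort(config)
  snaps <- assemble_snapshots(sim$cohort)
  outcomes <- detect_outcomes(sim$cohort)
  scores <- score_all(snaps, default_score_configs(systems))
  labeled <- labeled_score_matrix(scores, outcomes, kind = kind)
  cmp <- compare_all_systems(labeled, systems = systems)
  cmp$auc |>
    mutate(seed = config$seed, drift_scale = config$drift_scale,
           n_patients = config$n_patients)
}

#' Drift-recovery analysis across drift scales and seeds
#'
#' Runs [simulated_cohort_aucs()] over a grid of drift multipliers and seeds
#' with all other generator settings at their defaults.
#'
#' @param n_patients Cohort size per cell.
#' @param drift_scales Drift multipliers (default 0, 1, 2).
#' @param seeds Seeds, one cohort per seed per scale.
#' @param prevalence Deterioration prevalence.
#' @return Long tibble of per-cell AUC rows.
#' @export
drift_recovery_analysis <- function(n_patients = 2000,
                                    drift_scales = c(0, 1, 2),
                                    seeds = 1:5,
                                    prevalence = 0.05) {
  bind_rows(lapply(drift_scales, function(ds) {
    bind_rows(lapply(seeds, function(s) {
      simulated_cohort_aucs(sim_config(
        n_patients = n_patients, deterioration_prevalence = prevalence,
        drift_scale = ds, seed = s))
    }))
  }))
}

#' Null calibration of the AUC confidence interval
#'
#' With drift disabled the scores carry no information about the outcome, so
#' the DeLong 95% CI should cover 0.5 in about 95% of replicates. Returns
#' per-replicate coverage indicators for each system.
#'
#' @param n_patients Cohort size per replicate.
#' @param n_replicates Number of seeded replicates.
#' @param prevalence Deterioration prevalence.
#' @param seed_offset Added to the replicate index to form each seed.
#' @return Tibble with `seed`, `system`, `auc`, `covers_half`.
#' @export
null_calibration_analysis <- function(n_patients = 500, n_replicates = 20,
                                      prevalence = 0.05, seed_offset = 100) {
  bind_rows(lapply(seq_len(n_replicates), function(r) {
    auc <- simulated_cohort_aucs(sim_config(
      n_patients = n_patients, deterioration_prevalence = prevalence,
      drift_scale = 0, seed = seed_offset + r))
    auc |>
      mutate(covers_half = .data$ci_lower <= 0.5 & .data$ci_upper >= 0.5) |>
      select("system", "auc", "covers_half") |>
      mutate(seed = seed_offset + r)
  }))
}

#' Empirical type-I error of the paired DeLong test
#'
#' Simulates replicates of two independent noise scores against random
#' labels and reports the fraction of two-sided p-values below `alpha`.
#'
#' @param n_replicates Number of replicates.
#' @param n Observations per replicate.
#' @param alpha Nominal level.
#' @param seed Seed.
#' @return Rejection fraction (a single number).
#' @export
delong_type1_error <- function(n_replicates = 1000, n = 200, alpha = 0.05,
                               seed = 1) {
  set.seed(seed)
  rejections <- vapply(seq_len(n_replicates), function(i) {
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    delong_compare(a, b, labels)$p_value < alpha
  }, logical(1))
  mean(rejections)
}

#' Bootstrap standard error of the AUC
#'
#' Nonparametric bootstrap over observations; used to cross-check the DeLong
#' analytic standard error.
#'
#' @param scores,labels As in [compute_auc()].
#' @param n_boot Number of resamples.
#' @param seed Seed.
#' @return Bootstrap standard error of the AUC estimate.
#' @export
bootstrap_auc_se <- function(scores, labels, n_boot = 500, seed = 1) {
  set.seed(seed)
  n <- length(scores)
  reps <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(labels[idx])) < 2) return(NA_real_)
    delong_components(scores[idx], labels[idx])$theta
  }, numeric(1))
  stats::sd(reps, na.rm = TRUE)
}
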