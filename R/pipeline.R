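# Configuration-driven orchestration: simulate (or read) -> score ->
# phenotype -> evaluate -> report, with a reproducibility manifest.

#' Pipeline run configuration
#'
#' @param input Either a `sim_config` (the cohort is simulated) or a
#'   directory of cohort CSVs.
#' @param systems Scoring systems to run (subset of the five built-ins).
#' @param outcome Outcome kind(s) to evaluate (`"DETERIORATION"`,
#'   `"INFECTION"`).
#' @param horizon_hours Forward labeling window.
#' @param outdir Output directory.
#' @param seed Seed used for any run-level randomness (surrogate model).
#' @param fit_risk_model If `TRUE`, fit the surrogate continuous risk model
#'   and include it in the comparison.
#' @return A `run_config` list.
#' @export
run_config <- function(input, systems = SCORE_SYSTEMS,
                       outcome = "DETERIORATION", horizon_hours = 24,
                       outdir = tempfile("ews_run_"), seed = 1L,
                       fit_risk_model = FALSE) {
  systems <- toupper(systems)
  unknown <- setdiff(systems, SCORE_SYSTEMS)
  if (length(unknown) > 0) {
    stop("unknown score system(s): ", paste(unknown, collapse = ", "))
  }
  if (!inherits(input, "sim_config") &&
      !(is.character(input) && dir.exists(input))) {
    stop("input must be a sim_config or an existing cohort directory")
  }
  structure(list(input = input, systems = systems, outcome = outcome,
                 horizon_hours = horizon_hours, outdir = outdir,
                 seed = as.integer(seed), fit_risk_model = fit_risk_model),
            class = "run_config")
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  out <- df
  for (col in names(out)) {
    if (inherits(out[[col]], "POSIXct")) out[[col]] <- format_time(out[[col]])
  }
  readr::write_csv(out, path, progress = FALSE)
  path
}

#' Run the full evaluation pipeline
#'
#' Simulates or reads a cohort, assembles snapshots, computes every
#' configured score, phenotypes outcomes, labels observations over the
#' forward window, and writes the full report bundle (`scores.csv`,
#' `outcomes.csv`, `auc.csv`, `delong_matrix.csv`, `threshold_table.csv`,
#' `efficiency_curve.csv`, `cohort_summary.csv`) plus `manifest.json` with
#' per-stage counts and file checksums. Rerunning with the same config and
#' inputs reproduces identical tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory bundle (`cohort`, `scores`,
#'   `outcomes`, `labeled`, `comparison`, `summary`, `paths`, `log`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list()

  if (inherits(config$input, "sim_config")) {
    sim <- simulate_cohort(config$input)
    cohort <- sim$cohort
    write_ground_truth(sim$ground_truth, config$outdir)
  } else {
    cohort <- read_cohort(config$input)
  }
  log$n_patients <- nrow(cohort$encounters)
  log$n_vital_events <- nrow(cohort$vitals)
  log$n_rejected_rows <- nrow(cohort$rejects)

  issues <- validate_cohort(cohort)
  if (nrow(issues) > 0) {
    stop("stage 'validate' failed for patient(s): ",
         paste(utils::head(unique(issues$patient_id), 5), collapse = ", "))
  }

  snapshots <- assemble_snapshots(cohort)
  log$n_snapshots <- nrow(snapshots)

  outcomes <- detect_outcomes(cohort)
  log$n_deterioration_events <- sum(outcomes$kind == "DETERIORATION")
  log$n_infection_events <- sum(outcomes$kind == "INFECTION")

  configs <- default_score_configs(config$systems)
  scores <- score_all(snapshots, configs)

  labeled <- labeled_score_matrix(scores, outcomes, kind = config$outcome,
                                  horizon_hours = config$horizon_hours)
  log$n_excluded_after_event <- attr(labeled, "n_excluded")
  log$n_positive_observations <- sum(labeled$label)

  risk_model <- NULL
  if (config$fit_risk_model && sum(labeled$label) > 0 &&
      sum(labeled$label == 0) > 0) {
    snap_lab <- labeled |>
      select("patient_id", "time", "label") |>
      inner_join(snapshots, by = c("patient_id", "time"))
    risk_model <- fit_surrogate_risk_model(snap_lab, snap_lab$label,
                                           seed = config$seed)
    labeled$RISK_MODEL <- predict_risk(risk_model, snap_lab)
  }

  if (sum(labeled$label) > 0 && sum(labeled$label == 0) > 0) {
    comparison <- compare_all_systems(labeled)
  } else {
    # single-class labels (e.g. an event-free small cohort): emit the empty
    # report shapes rather than failing the run
    warning("labels are single-class; comparison tables will be empty")
    comparison <- list(
      auc = tibble(system = character(), auc = numeric(),
                   variance = numeric(), ci_lower = numeric(),
                   ci_upper = numeric(), n_pos = integer(), n_neg = integer()),
      delong = tibble(system_a = character(), system_b = character(),
                      auc_a = numeric(), auc_b = numeric(),
                      difference = numeric(), z = numeric(),
                      p_value = numeric()),
      delong_p = matrix(numeric(), 0, 0),
      thresholds = tibble(system = character(), threshold = numeric(),
                          tp = integer(), fp = integer(), tn = integer(),
                          fn = integer(), sensitivity = numeric(),
                          specificity = numeric(), ppv = numeric(),
                          npv = numeric()),
      efficiency = tibble(system = character(), threshold = numeric(),
                          alert_fraction = numeric(), sensitivity = numeric()))
  }
  summary_tbl <- summarize_cohort(cohort, outcomes, kind = config$outcome)

  paths <- c(
    scores = write_table(scores |> select(-any_of("components")),
                         config$outdir, "scores.csv"),
    outcomes = write_table(outcomes, config$outdir, "outcomes.csv"),
    auc = write_table(comparison$auc, config$outdir, "auc.csv"),
    delong_matrix = write_table(comparison$delong, config$outdir,
                                "delong_matrix.csv"),
    threshold_table = write_table(comparison$thresholds, config$outdir,
                                  "threshold_table.csv"),
    efficiency_curve = write_table(comparison$efficiency, config$outdir,
                                   "efficiency_curve.csv"),
    cohort_summary = write_table(summary_tbl, config$outdir,
                                 "cohort_summary.csv")
  )

  manifest <- list(
    package = "obsews",
    version = as.character(utils::packageVersion("obsews")),
    seed = config$seed,
    systems = config$systems,
    outcome = config$outcome,
    horizon_hours = config$horizon_hours,
    counts = log,
    files = as.list(tools::md5sum(unname(paths)))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, snapshots = snapshots, scores = scores,
                 outcomes = outcomes, labeled = labeled,
                 comparison = comparison, summary = summary_tbl,
                 risk_model = risk_model, paths = paths, log = log))
}

read_bundle_csv <- function(dir, name) {
  path <- file.path(dir, name)
  if (!file.exists(path)) return(NULL)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Render a human-readable markdown report from a run bundle
#'
#' Pure presentation: reads the CSV tables written by [run_pipeline()] and
#' assembles a markdown summary (AUC ranking with CIs, pairwise comparisons,
#' threshold accuracy, efficiency curves). Nothing is recomputed; missing
#' tables are listed as missing.
#'
#' @param outdir Directory containing the run bundle.
#' @param file Output markdown path (default `report.md` inside `outdir`).
#' @return Invisibly, the path to the written report.
#' @export
render_report <- function(outdir, file = file.path(outdir, "report.md")) {
  lines <- c("# Early warning score comparison report", "")
  auc <- read_bundle_csv(outdir, "auc.csv")
  if (is.null(auc)) {
    lines <- c(lines, "AUC table: not available", "")
  } else {
    lines <- c(lines, "## Discrimination (AUC, DeLong 95% CI)", "",
               "| system | AUC | 95% CI | n pos | n neg |",
               "|---|---|---|---|---|",
               sprintf("| %s | %.3f | %.3f-%.3f | %d | %d |",
                       auc$system, auc$auc, auc$ci_lower, auc$ci_upper,
                       auc$n_pos, auc$n_neg),
               "")
  }
  dl <- read_bundle_csv(outdir, "delong_matrix.csv")
  if (is.null(dl)) {
    lines <- c(lines, "Pairwise comparisons: not available", "")
  } else if (nrow(dl) > 0) {
    lines <- c(lines, "## Pairwise DeLong comparisons", "",
               "| A | B | AUC A | AUC B | difference | p |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %.3f | %.3f | %+.3f | %.3g |",
                       dl$system_a, dl$system_b, dl$auc_a, dl$auc_b,
                       dl$difference, dl$p_value),
               "")
  }
  thr <- read_bundle_csv(outdir, "threshold_table.csv")
  if (is.null(thr)) {
    lines <- c(lines, "Threshold table: not available", "")
  } else {
    lines <- c(lines, "## Accuracy at score thresholds", "",
               "| system | threshold | sens | spec | PPV | NPV |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %g | %.2f | %.2f | %.3f | %.3f |",
                       thr$system, thr$threshold, thr$sensitivity,
                       thr$specificity, thr$ppv, thr$npv),
               "")
  }
  eff <- read_bundle_csv(outdir, "efficiency_curve.csv")
  if (is.null(eff) || nrow(eff) == 0) {
    lines <- c(lines, "Efficiency curves: not available", "")
  } else {
    lines <- c(lines, "## Efficiency (alert burden vs sensitivity)", "",
               "| system | threshold | alert fraction | sensitivity |",
               "|---|---|---|---|",
               sprintf("| %s | %g | %.3f | %.2f |", eff$system,
                       eff$threshold, eff$alert_fraction, eff$sensitivity),
               "")
  }
  writeLines(lines, file)
  invisible(file)
}

#' Plot efficiency curves
#' @param efficiency Efficiency tibble from [compare_all_systems()].
#' @return A ggplot object.
#' @export
plot_efficiency_curves <- function(efficiency) {
  ggplot2::ggplot(efficiency,
                  ggplot2::aes(x = .data$sensitivity,
                               y = .data$alert_fraction,
                               colour = .data$system)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Sensitivity",
                  y = "Fraction of observations alerting",
                  colour = "System") +
    ggplot2::theme_minimal()
}

#' Plot an AUC forest (point estimate and 95% CI per system)
#' @param auc AUC tibble from [compare_all_systems()].
#' @return A ggplot object.
#' @export
plot_auc_forest <- function(auc) {
  ggplot2::ggplot(auc, ggplot2::aes(x = .data$auc,
                                    y = stats::reorder(.data$system, .data$auc))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "AUC (DeLong 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
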