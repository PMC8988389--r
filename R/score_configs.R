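# Declarative threshold-band score configurations.
#
# A band is an interval on one variable with explicit open/closed endpoints
# and either an integer point weight (aggregate systems: MEWS, NEWS) or a
# severity level (trigger systems: MEOWS red/yellow, MEWT severe/nonsevere,
# MEWC criterion). Point-system bands must tile the whole real line per
# variable; trigger-system bands only mark the abnormal regions.
#
# AVPU is scored on its numeric coding A=0, V=1, P=2, U=3; SUPP_O2 on 0/1.
# MAP is a derived variable, (SBP + 2 DBP) / 3, computed at scoring time.

SCORE_SYSTEMS <- c("MEWS", "NEWS", "MEOWS", "MEWC", "MEWT")
COMBINATION_RULES <- c(MEWS = "SUM_POINTS", NEWS = "SUM_POINTS",
                       MEOWS = "RED_YELLOW", MEWC = "ANY_CRITERION",
                       MEWT = "SEVERE_NONSEVERE")

# half-open [lower, upper) band for point systems
po_band <- function(variable, lower, upper, points) {
  tibble(variable = variable, lower = lower, upper = upper,
         lower_closed = is.finite(lower), upper_closed = FALSE,
         points = as.integer(points), level = NA_character_)
}

# trigger band with explicit endpoint closure
tr_band <- function(variable, lower, upper, level,
                    lower_closed = is.finite(lower),
                    upper_closed = is.finite(upper)) {
  tibble(variable = variable, lower = lower, upper = upper,
         lower_closed = lower_closed, upper_closed = upper_closed,
         points = NA_integer_, level = level)
}

builtin_bands <- function(system) {
  switch(system,
    # Subbe et al. aggregate bands; AVPU A/V/P/U -> 0/1/2/3 points.
    MEWS = bind_rows(
      po_band("RR",   -Inf,   9, 2), po_band("RR",     9,  15, 0),
      po_band("RR",     15,  21, 1), po_band("RR",    21,  30, 2),
      po_band("RR",     30, Inf, 3),
      po_band("HR",   -Inf,  40, 2), po_band("HR",    40,  51, 1),
      po_band("HR",     51, 101, 0), po_band("HR",   101, 111, 1),
      po_band("HR",    111, 130, 2), po_band("HR",   130, Inf, 3),
      po_band("SBP",  -Inf,  71, 3), po_band("SBP",   71,  81, 2),
      po_band("SBP",    81, 101, 1), po_band("SBP",  101, 200, 0),
      po_band("SBP",   200, Inf, 2),
      po_band("TEMP", -Inf,  35, 2), po_band("TEMP",  35, 38.5, 0),
      po_band("TEMP", 38.5, Inf, 2),
      po_band("AVPU", -Inf,   1, 0), po_band("AVPU",   1,   2, 1),
      po_band("AVPU",    2,   3, 2), po_band("AVPU",   3, Inf, 3)
    ),
    # National early warning score bands; not-alert scores 3.
    NEWS = bind_rows(
      po_band("RR",   -Inf,   9, 3), po_band("RR",     9,  12, 1),
      po_band("RR",     12,  21, 0), po_band("RR",    21,  25, 2),
      po_band("RR",     25, Inf, 3),
      po_band("SPO2", -Inf,  92, 3), po_band("SPO2",  92,  94, 2),
      po_band("SPO2",   94,  96, 1), po_band("SPO2",  96, Inf, 0),
      po_band("SUPP_O2", -Inf, 1, 0), po_band("SUPP_O2", 1, Inf, 2),
      po_band("TEMP", -Inf, 35.1, 3), po_band("TEMP", 35.1, 36.1, 1),
      po_band("TEMP", 36.1, 38.1, 0), po_band("TEMP", 38.1, 39.1, 1),
      po_band("TEMP", 39.1, Inf, 2),
      po_band("SBP",  -Inf,  91, 3), po_band("SBP",   91, 101, 2),
      po_band("SBP",   101, 111, 1), po_band("SBP",  111, 220, 0),
      po_band("SBP",   220, Inf, 3),
      po_band("HR",   -Inf,  41, 3), po_band("HR",    41,  51, 1),
      po_band("HR",     51,  91, 0), po_band("HR",    91, 111, 1),
      po_band("HR",    111, 131, 2), po_band("HR",   131, Inf, 3),
      po_band("AVPU", -Inf,   1, 0), po_band("AVPU",   1, Inf, 3)
    ),
    # Singh et al. red/yellow trigger bands.
    MEOWS = bind_rows(
      tr_band("RR",   -Inf,  10, "RED", upper_closed = FALSE),
      tr_band("RR",     21,  30, "YELLOW"),
      tr_band("RR",     30, Inf, "RED", lower_closed = FALSE),
      tr_band("HR",   -Inf,  40, "RED", upper_closed = FALSE),
      tr_band("HR",     40,  50, "YELLOW"),
      tr_band("HR",    100, 120, "YELLOW"),
      tr_band("HR",    120, Inf, "RED", lower_closed = FALSE),
      tr_band("SBP",  -Inf,  90, "RED", upper_closed = FALSE),
      tr_band("SBP",    90, 100, "YELLOW"),
      tr_band("SBP",   150, 160, "YELLOW"),
      tr_band("SBP",   160, Inf, "RED", lower_closed = FALSE),
      tr_band("DBP",    90, 100, "YELLOW"),
      tr_band("DBP",   100, Inf, "RED", lower_closed = FALSE),
      tr_band("TEMP", -Inf,  35, "RED", upper_closed = FALSE),
      tr_band("TEMP",   35,  36, "YELLOW"),
      tr_band("TEMP",   38, Inf, "RED", lower_closed = FALSE),
      tr_band("SPO2", -Inf,  95, "RED", upper_closed = FALSE),
      tr_band("AVPU",    1,   1, "YELLOW"),
      tr_band("AVPU",    2,   3, "RED")
    ),
    # Mhyre et al. single-parameter criteria. Oliguria (< 35 mL/h over the
    # charted 12 h window, i.e. < 420 mL/12 h) applies only to quantified
    # (> 0) urine outputs because unquantified urine is charted as 0.
    MEWC = bind_rows(
      tr_band("SBP",  -Inf,  90, "CRITERION", upper_closed = FALSE),
      tr_band("SBP",   160, Inf, "CRITERION", lower_closed = FALSE),
      tr_band("DBP",   100, Inf, "CRITERION", lower_closed = FALSE),
      tr_band("HR",   -Inf,  50, "CRITERION", upper_closed = FALSE),
      tr_band("HR",    120, Inf, "CRITERION", lower_closed = FALSE),
      tr_band("RR",   -Inf,  10, "CRITERION", upper_closed = FALSE),
      tr_band("RR",     30, Inf, "CRITERION", lower_closed = FALSE),
      tr_band("SPO2", -Inf,  95, "CRITERION", upper_closed = FALSE),
      tr_band("URINE_OUT", 0, 420, "CRITERION",
              lower_closed = FALSE, upper_closed = FALSE)
    ),
    # Shields et al. severe / non-severe triggers; MAP derived from SBP/DBP.
    MEWT = bind_rows(
      tr_band("HR",    130, Inf, "SEVERE", lower_closed = FALSE),
      tr_band("HR",    110, 130, "NONSEVERE",
              lower_closed = FALSE, upper_closed = TRUE),
      tr_band("HR",   -Inf,  50, "NONSEVERE", upper_closed = FALSE),
      tr_band("RR",     30, Inf, "SEVERE", lower_closed = FALSE),
      tr_band("RR",     24,  30, "NONSEVERE",
              lower_closed = FALSE, upper_closed = TRUE),
      tr_band("RR",   -Inf,  12, "NONSEVERE", upper_closed = FALSE),
      tr_band("MAP",  -Inf,  55, "SEVERE", upper_closed = FALSE),
      tr_band("SPO2", -Inf,  90, "SEVERE", upper_closed = FALSE),
      tr_band("SPO2",   90,  93, "NONSEVERE", upper_closed = FALSE),
      tr_band("TEMP",   38, Inf, "NONSEVERE"),
      tr_band("TEMP", -Inf,  36, "NONSEVERE"),
      tr_band("SBP",   155, Inf, "NONSEVERE", lower_closed = FALSE),
      tr_band("SBP",  -Inf,  80, "NONSEVERE", upper_closed = FALSE),
      tr_band("DBP",   105, Inf, "NONSEVERE", lower_closed = FALSE),
      tr_band("DBP",  -Inf,  45, "NONSEVERE", upper_closed = FALSE),
      tr_band("FHR",   160, Inf, "NONSEVERE", lower_closed = FALSE)
    ),
    stop("unknown score system: ", system)
  )
}

#' Load a score configuration
#'
#' Returns the validated threshold-band configuration for one scoring system,
#' either a shipped built-in (`"mews"`, `"news"`, `"meows"`, `"mewc"`,
#' `"mewt"`) or a YAML file with the same structure. Band overlap and (for
#' point systems) real-line coverage are checked at load time.
#'
#' @param name_or_path Built-in system name (case-insensitive) or path to a
#'   YAML config file.
#' @return An `ews_score_config`: list with `system`, `rule`,
#'   `trigger_threshold` and a `bands` tibble (`variable`, `lower`, `upper`,
#'   `lower_closed`, `upper_closed`, `points`, `level`).
#' @export
load_score_config <- function(name_or_path) {
  nm <- toupper(name_or_path)
  if (nm %in% SCORE_SYSTEMS) {
    cfg <- structure(
      list(system = nm, rule = unname(COMBINATION_RULES[nm]),
           trigger_threshold = switch(unname(COMBINATION_RULES[nm]),
                                      SUM_POINTS = if (nm == "MEWS") 4L else 5L,
                                      RED_YELLOW = 2L,
                                      SEVERE_NONSEVERE = 2L,
                                      ANY_CRITERION = 1L),
           bands = builtin_bands(nm)),
      class = "ews_score_config")
    return(validate_score_config(cfg))
  }
  if (!file.exists(name_or_path)) {
    stop("unknown score system or missing config file: ", name_or_path)
  }
  raw <- yaml::read_yaml(name_or_path)
  bands <- bind_rows(lapply(raw$bands, function(b) {
    tibble(variable = toupper(b[["variable"]]),
           lower = if (is.null(b[["lower"]])) -Inf else as.numeric(b[["lower"]]),
           upper = if (is.null(b[["upper"]])) Inf else as.numeric(b[["upper"]]),
           lower_closed = isTRUE(b[["lower_closed"]]),
           upper_closed = isTRUE(b[["upper_closed"]]),
           points = if (is.null(b[["points"]])) NA_integer_ else
             as.integer(b[["points"]]),
           level = if (is.null(b[["level"]])) NA_character_ else
             toupper(b[["level"]]))
  }))
  cfg <- structure(
    list(system = toupper(raw$system), rule = toupper(raw$rule),
         trigger_threshold = as.integer(raw$trigger_threshold %||% 1L),
         bands = bands),
    class = "ews_score_config")
  validate_score_config(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a score configuration to YAML
#' @param config An `ews_score_config`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_score_config <- function(config, path) {
  bands <- lapply(seq_len(nrow(config$bands)), function(i) {
    b <- as.list(config$bands[i, ])
    b <- b[!vapply(b, function(x) is.na(x) || (is.numeric(x) && !is.finite(x)), logical(1))]
    b
  })
  yaml::write_yaml(list(system = config$system, rule = config$rule,
                        trigger_threshold = config$trigger_threshold,
                        bands = bands), path)
  invisible(path)
}

band_allows <- function(band, v) {
  lo_ok <- if (band$lower_closed) v >= band$lower else v > band$lower
  hi_ok <- if (band$upper_closed) v <= band$upper else v < band$upper
  lo_ok & hi_ok
}

bands_overlap <- function(a, b) {
  # intervals intersect iff each starts before the other ends, with closure
  lo <- max(a$lower, b$lower); hi <- min(a$upper, b$upper)
  if (lo < hi) return(TRUE)
  if (lo > hi) return(FALSE)
  # touching at a point: overlap iff that point is included by both
  a_cl <- if (lo == a$lower) a$lower_closed else a$upper_closed
  b_cl <- if (lo == b$lower) b$lower_closed else b$upper_closed
  a_cl && b_cl
}

#' Validate a score configuration
#'
#' Checks the variable vocabulary, the non-overlap of bands within each
#' variable, and — for point systems — that the bands jointly cover the whole
#' real line with no gap (a zero-point band must exist for normal values).
#'
#' @param config An `ews_score_config`.
#' @return The config, invisibly-valid; errors describe the offending
#'   variable and bands.
#' @export
validate_score_config <- function(config) {
  known <- c(VITAL_VARIABLES, LAB_ANALYTES, "MAP")
  bands <- config$bands
  bad <- setdiff(unique(bands$variable), known)
  if (length(bad) > 0) {
    stop("unknown_variable: ", paste(bad, collapse = ", "))
  }
  is_points <- config$rule == "SUM_POINTS"
  if (is_points && any(is.na(bands$points))) {
    stop("point system '", config$system, "' has bands without points")
  }
  for (var in unique(bands$variable)) {
    vb <- bands[bands$variable == var, ]
    vb <- vb[order(vb$lower, vb$upper), ]
    if (nrow(vb) > 1) {
      for (i in seq_len(nrow(vb) - 1)) {
        for (j in seq(i + 1, nrow(vb))) {
          if (bands_overlap(vb[i, ], vb[j, ])) {
            stop(sprintf("overlapping bands for %s in %s: [%s,%s] and [%s,%s]",
                         var, config$system, vb$lower[i], vb$upper[i],
                         vb$lower[j], vb$upper[j]))
          }
        }
      }
    }
    if (is_points) {
      if (!is.infinite(vb$lower[1]) || !is.infinite(vb$upper[nrow(vb)])) {
        stop(sprintf("coverage gap for %s in %s: line not covered at extremes",
                     var, config$system))
      }
      if (nrow(vb) > 1) {
        for (i in seq_len(nrow(vb) - 1)) {
          gap <- vb$upper[i] != vb$lower[i + 1] ||
            !(xor(vb$upper_closed[i], vb$lower_closed[i + 1]))
          if (gap) {
            stop(sprintf("coverage gap for %s in %s between %s and %s",
                         var, config$system, vb$upper[i], vb$lower[i + 1]))
          }
        }
      }
    }
  }
  config
}

#' Load all built-in score configurations
#' @param systems Character vector of system names (default all five).
#' @return Named list of `ews_score_config` objects.
#' @export
default_score_configs <- function(systems = SCORE_SYSTEMS) {
  setNames(lapply(systems, load_score_config), toupper(systems))
}

#' @export
print.ews_score_config <- function(x, ...) {
  cat(sprintf("<ews_score_config> %s (%s), %d bands over %d variables\n",
              x$system, x$rule, nrow(x$bands),
              length(unique(x$bands$variable))))
  invisible(x)
}
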