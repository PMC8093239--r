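#' Band a K10 total score into distress categories
#'
#' Maps a Kessler Psychological Distress Scale (K10) summed score (10-50)
#' onto the established screening categories: psychologically well
#' (score < 20), mild (20-24), moderate (25-29) or severe (>= 30)
#' psychological distress. A score of exactly 20 belongs to the mild band,
#' the standard K10 convention.
#'
#' @param score Integer vector of K10 totals, each in 10-50.
#' @param cutpoints Lower bounds of the mild, moderate and severe bands
#'   (default `c(20, 25, 30)`).
#' @return Character vector of states in
#'   `c("well", "mild", "moderate", "severe")`.
#' @examples
#' k10_band(c(15, 22, 27, 30))
#' @export
k10_band <- function(score, cutpoints = c(20, 25, 30)) {
  check_score_range(score, 10, 50, "K10")
  states <- c("well", "mild", "moderate", "severe")
  states[findInterval(score, cutpoints) + 1L]
}

#' Band a PSQI global score into sleep-quality categories
#'
#' Pittsburgh Sleep Quality Index global scores range 0-21; scores of 5 or
#' below indicate good sleep patterns and quality.
#'
#' @param score Integer vector of PSQI totals, each in 0-21.
#' @param cutoff Highest score still classed as good sleep (default 5).
#' @return Character vector of states in `c("good", "poor")`.
#' @examples
#' psqi_band(c(0, 5, 6))
#' @export
psqi_band <- function(score, cutoff = 5) {
  check_score_range(score, 0, 21, "PSQI")
  c("good", "poor")[(score > cutoff) + 1L]
}

#' Dichotomize a score at the midpoint of its theoretical range
#'
#' For instruments without validated clinical cutoffs, scores are split at
#' the 50th percentile of the *possible* range of the measure: states are
#' `low` for scores strictly below the midpoint and `high` for scores at
#' or above it (the boundary belongs to the upper band). Optional labels
#' rename the two states to instrument-specific vocabulary.
#'
#' @param score Numeric vector, each value within `[scale_min, scale_max]`.
#' @param scale_min,scale_max Theoretical bounds of the instrument score.
#' @param labels Length-2 character vector naming the below-midpoint and
#'   at-or-above-midpoint states (default `c("low", "high")`).
#' @return Character vector of states.
#' @examples
#' midpoint_band(c(44, 45, 52), 15, 75)            # midpoint 45
#' midpoint_band(18, 3, 21, labels = c("less", "more"))
#' @export
midpoint_band <- function(score, scale_min, scale_max,
                          labels = c("low", "high")) {
  stopifnot(scale_min < scale_max, length(labels) == 2L)
  check_score_range(score, scale_min, scale_max, "score")
  mid <- (scale_min + scale_max) / 2
  labels[(score >= mid) + 1L]
}

check_score_range <- function(score, lo, hi, what) {
  bad <- which(!is.na(score) & (score < lo | score > hi))
  if (length(bad)) {
    stop(what, " score out of range [", lo, ", ", hi, "]: ",
         paste(score[bad], collapse = ", "), call. = FALSE)
  }
  invisible(score)
}

#' Default discretization rules for the distress network
#'
#' One rule per network node, mapping a raw-score column of the cohort
#' table onto that node's states. K10 and PSQI use validated banded
#' cutoffs; the remaining instruments, which lack validated ranges, are
#' dichotomized at the midpoint of their theoretical score range; the
#' cyberstrife flag passes through. Theoretical ranges for the midpoint
#' instruments are package defaults and can be overridden per deployment
#' via the `ranges` argument (or a run-config file).
#'
#' @param ranges Optional named list overriding instrument score ranges,
#'   e.g. `list(scs_total = c(15, 90))`.
#' @return Named list of rule objects keyed by network node name. Each rule
#'   has fields `node`, `column`, `kind`
#'   (`"banded"`, `"threshold"`, `"midpoint"` or `"passthrough"`) and the
#'   kind-specific parameters.
#' @export
default_discretization_rules <- function(ranges = list()) {
  rng <- list(
    k10_total = c(10, 50), psqi_total = c(0, 21), scs_total = c(15, 90),
    pa_score = c(3, 21), eat_score = c(6, 42), mcqa_total = c(30, 120),
    maas_total = c(14, 84), bis_total = c(8, 32),
    qol_physical = c(0, 100), qol_social = c(0, 100), qol_psych = c(0, 100))
  for (nm in names(ranges)) rng[[nm]] <- ranges[[nm]]

  mid_rule <- function(node, column, labels) {
    list(node = node, column = column, kind = "midpoint",
         scale_min = rng[[column]][1L], scale_max = rng[[column]][2L],
         labels = labels)
  }
  rules <- list(
    psychological_distress = list(
      node = "psychological_distress", column = "k10_total", kind = "banded",
      scale_min = 10, scale_max = 50, cutpoints = c(20, 25, 30),
      states = c("well", "mild", "moderate", "severe")),
    sleep = list(
      node = "sleep", column = "psqi_total", kind = "threshold",
      scale_min = 0, scale_max = 21, cutoff = 5,
      states = c("good", "poor")),
    physical_activity = mid_rule("physical_activity", "pa_score",
                                 c("less", "more")),
    eating_behaviours = mid_rule("eating_behaviours", "eat_score",
                                 c("less_healthy", "more_healthy")),
    social_connectedness = mid_rule("social_connectedness", "scs_total",
                                    c("low", "high")),
    mindfulness = mid_rule("mindfulness", "maas_total", c("less", "more")),
    metacognition = mid_rule("metacognition", "mcqa_total", c("low", "high")),
    impulsivity = mid_rule("impulsivity", "bis_total", c("low", "high")),
    qol_physical = mid_rule("qol_physical", "qol_physical", c("low", "high")),
    qol_social = mid_rule("qol_social", "qol_social", c("low", "high")),
    qol_psych = mid_rule("qol_psych", "qol_psych", c("low", "high")),
    cyberstrife = list(
      node = "cyberstrife", column = "cyberstrife", kind = "passthrough",
      states = c("no", "yes")))
  for (r in rules) check_rule(r)
  rules
}

# A rule must partition its score range: strictly increasing cutpoints, one
# state per band, no gaps or overlaps (total by construction of
# findInterval; asserted here at load time).
check_rule <- function(rule) {
  kind <- rule$kind
  if (kind == "banded") {
    stopifnot(!is.unsorted(rule$cutpoints, strictly = TRUE),
              length(rule$states) == length(rule$cutpoints) + 1L,
              rule$cutpoints[1L] > rule$scale_min,
              rule$cutpoints[length(rule$cutpoints)] <= rule$scale_max)
  } else if (kind == "threshold") {
    stopifnot(length(rule$states) == 2L,
              rule$cutoff >= rule$scale_min, rule$cutoff < rule$scale_max)
  } else if (kind == "midpoint") {
    stopifnot(rule$scale_min < rule$scale_max, length(rule$labels) == 2L)
  } else if (kind != "passthrough") {
    stop("unknown rule kind: ", kind, call. = FALSE)
  }
  invisible(rule)
}

apply_rule <- function(rule, x) {
  switch(rule$kind,
    banded = {
      check_score_range(x, rule$scale_min, rule$scale_max, rule$column)
      rule$states[findInterval(x, rule$cutpoints) + 1L]
    },
    threshold = {
      check_score_range(x, rule$scale_min, rule$scale_max, rule$column)
      rule$states[(x > rule$cutoff) + 1L]
    },
    midpoint = midpoint_band(x, rule$scale_min, rule$scale_max, rule$labels),
    passthrough = rule$states[as.logical(x) + 1L],
    stop("unknown rule kind: ", rule$kind, call. = FALSE))
}

#' Discretize a raw cohort into network node states
#'
#' Applies one discretization rule per network node to each participant's
#' raw instrument scores. Records with any missing score are excluded
#' (complete-case analysis); the number dropped is reported via a message
#' and attached as the attribute `n_dropped`.
#'
#' @param raw Data frame of raw records: a `participant_id` column plus the
#'   score columns named by the rules (see [read_cohort_csv()] for the
#'   cohort CSV dialect).
#' @param rules Named list of rules from [default_discretization_rules()].
#' @return Data frame (`participant_id` + one character state column per
#'   node) with attribute `n_dropped`.
#' @examples
#' raw <- fixture_raw_cohort()
#' coh <- discretize_cohort(raw, default_discretization_rules())
#' table(coh$psychological_distress)
#' @export
discretize_cohort <- function(raw, rules) {
  stopifnot(is.data.frame(raw))
  if (!"participant_id" %in% names(raw)) {
    stop("raw cohort must have a 'participant_id' column", call. = FALSE)
  }
  cols <- vapply(rules, `[[`, character(1), "column")
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols)) {
    stop("raw cohort lacks column(s) required by the rules: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  complete <- stats::complete.cases(raw[, unique(cols), drop = FALSE])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message("discretize_cohort: dropped ", n_dropped,
            " record(s) with missing scores (complete-case)")
  }
  raw <- raw[complete, , drop = FALSE]
  out <- data.frame(participant_id = raw$participant_id,
                    stringsAsFactors = FALSE)
  for (nm in names(rules)) {
    out[[nm]] <- apply_rule(rules[[nm]], raw[[rules[[nm]]$column]])
  }
  attr(out, "n_dropped") <- n_dropped
  out
}
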