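#' Percent change of a probability relative to baseline
#'
#' The scenario statistic: the relative change, in percent, of a state's
#' probability after evidence is introduced,
#' \deqn{\Delta_{\%} = \frac{P_{evidence} - P_{baseline}}{P_{baseline}}
#'   \times 100.}
#' Both arguments must be on the same scale (both probabilities or both
#' percentages). A zero baseline leaves the statistic undefined and raises
#' an error rather than returning an infinity.
#'
#' @param p_baseline Baseline probability (or %), strictly positive.
#' @param p_evidence Probability (or %) under the scenario evidence.
#' @return Numeric percent change (vectorized).
#' @examples
#' percent_change(3, 21)   # 600
#' percent_change(2, 33)   # 1550
#' @export
percent_change <- function(p_baseline, p_evidence) {
  if (any(p_baseline < 0) || any(p_evidence < 0)) {
    stop("probabilities must be non-negative", call. = FALSE)
  }
  if (any(p_baseline == 0)) {
    stop("percent change is undefined for a zero baseline probability",
         call. = FALSE)
  }
  (p_evidence - p_baseline) / p_baseline * 100
}

#' Round half away from zero
#'
#' Integer rounding used by the report layer: 0.5 rounds up in magnitude
#' (so -26.5 prints as -27), unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @return Numeric vector of integers.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Define a named scenario
#'
#' A scenario is a named set of hard observations ("certainty" evidence) to
#' be propagated through the network.
#'
#' @param name Scenario label.
#' @param evidence Non-empty named character vector (node = state).
#' @return An object of class `bn_scenario`.
#' @seealso [preset_scenarios()], [run_scenario()]
#' @export
scenario <- function(name, evidence) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(evidence) == 0L) {
    stop("a scenario needs at least one evidence observation", call. = FALSE)
  }
  structure(list(name = name, evidence = unlist(evidence)),
            class = "bn_scenario")
}

#' Preset "certainty" scenarios over the default structure
#'
#' The four analyses reported for this model: certainty of psychological
#' wellness, certainty of severe psychological distress (both conditioning
#' the outcome node, i.e. backwards reasoning), certainty of less healthy
#' eating behaviours, and certainty of low social connectedness.
#'
#' @return Named list of `bn_scenario` objects.
#' @export
preset_scenarios <- function() {
  list(
    wellness = scenario(
      "certainty for psychological wellness",
      c(psychological_distress = "well")),
    severe_distress = scenario(
      "certainty for severe psychological distress",
      c(psychological_distress = "severe")),
    unhealthy_eating = scenario(
      "certainty for less healthy eating behaviours",
      c(eating_behaviours = "less_healthy")),
    low_social_connectedness = scenario(
      "certainty for low social connectedness",
      c(social_connectedness = "low")))
}

#' Propagate scenario evidence and compare with baseline
#'
#' Computes the baseline marginals of the network, the posterior marginals
#' under the scenario evidence, and the percent change of every node state,
#' on unrounded probabilities. Evidence nodes are flagged as instantiated.
#'
#' @param pnet A `distress_bn`.
#' @param scn A `bn_scenario`, or a named character vector of evidence.
#' @return A data frame of class `scenario_result` with columns `node`,
#'   `state`, `baseline`, `scenario` (probabilities), `delta_pct`
#'   (unrounded percent change; `NA` where the baseline is zero) and
#'   `instantiated`. The scenario name and evidence are carried as
#'   attributes.
#' @examples
#' net <- fit_network(generate_fixture_cohort(), default_network_spec())
#' res <- run_scenario(net, preset_scenarios()$unhealthy_eating)
#' head(render_scenario_table(res))
#' @export
run_scenario <- function(pnet, scn) {
  if (!inherits(scn, "bn_scenario")) scn <- scenario("scenario", scn)
  evidence <- as_evidence(scn$evidence, pnet$spec)
  base <- prior_marginals(pnet)
  post <- posterior(pnet, evidence)
  rows <- lapply(node_names(pnet$spec), function(v) {
    states <- pnet$spec[[v]]$states
    b <- base[[v]][states]
    p <- post[[v]][states]
    data.frame(node = v, state = states, baseline = as.numeric(b),
               scenario = as.numeric(p),
               delta_pct = ifelse(b > 0, (p - b) / b * 100, NA_real_),
               instantiated = v %in% names(evidence),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scenario_name") <- scn$name
  attr(out, "evidence") <- evidence
  class(out) <- c("scenario_result", class(out))
  out
}

#' Nodes materially affected by a scenario
#'
#' Lists the non-evidence nodes whose largest absolute per-state percent
#' change exceeds a tolerance, mirroring the "changes in affected nodes"
#' summaries of scenario reports.
#'
#' @param result A `scenario_result`.
#' @param tolerance Non-negative threshold on `|delta_pct|` (default 0).
#' @return Character vector of node names, in network order.
#' @export
affected_nodes <- function(result, tolerance = 0) {
  stopifnot(inherits(result, "scenario_result"), tolerance >= 0)
  free <- result[!result$instantiated & !is.na(result$delta_pct), ]
  mx <- tapply(abs(free$delta_pct), free$node, max)
  keep <- names(mx)[mx > tolerance]
  intersect(unique(result$node), keep)
}

#' Render a scenario result as a report table
#'
#' Formats probabilities as integer percentages (half away from zero) and
#' recomputes the printed percent change from those rounded percentages,
#' so the table is internally consistent at the printed precision — a
#' reader can reproduce every printed change cell from the printed
#' baseline and scenario columns. The unrounded statistic is retained in
#' `delta_pct_exact`. A printed baseline of 0% makes the printed change
#' undefined (`NA`).
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @return Data frame with columns `node`, `state`, `baseline_pct`,
#'   `scenario_pct`, `delta_pct` (printed, integer), `delta_pct_exact`
#'   and `instantiated`.
#' @export
render_scenario_table <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  b <- round_half_away(100 * result$baseline)
  s <- round_half_away(100 * result$scenario)
  printed <- ifelse(b > 0, round_half_away((s - b) / b * 100), NA_real_)
  data.frame(node = result$node, state = result$state,
             baseline_pct = b, scenario_pct = s,
             delta_pct = printed, delta_pct_exact = result$delta_pct,
             instantiated = result$instantiated, stringsAsFactors = FALSE)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario:", attr(x, "scenario_name"), "\n")
  ev <- attr(x, "evidence")
  cat("Evidence:", paste(names(ev), ev, sep = " = ", collapse = "; "), "\n\n")
  print(render_scenario_table(x), row.names = FALSE)
  invisible(x)
}
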