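#' Estimate a root node's prior from cohort frequencies
#'
#' The prior of a parentless node is the relative frequency of each of its
#' states in the discretized cohort.
#'
#' @param cohort Discretized cohort data frame (see [discretize_cohort()]).
#' @param node Node name (a column of `cohort`).
#' @param states Character vector of the node's states, in order.
#' @return Named probability vector over `states`, summing to 1.
#' @examples
#' coh <- generate_fixture_cohort()
#' fit_root_priors(coh, "physical_activity", c("less", "more"))
#' @export
fit_root_priors <- function(cohort, node, states) {
  x <- cohort_column(cohort, node, states)
  if (length(x) == 0L) {
    stop("cannot estimate priors for '", node, "' from an empty cohort",
         call. = FALSE)
  }
  counts <- vapply(states, function(s) sum(x == s), numeric(1))
  counts / sum(counts)
}

#' Estimate a conditional probability table from cohort frequencies
#'
#' For every full configuration of the parents' states, the child's
#' conditional distribution is the relative frequency of its states among
#' the cohort records matching that configuration (optionally with add-α
#' smoothing). Parent configurations never observed in the cohort get the
#' uniform distribution, keeping the CPT well defined without smoothing
#' the observed rows.
#'
#' @param cohort Discretized cohort data frame.
#' @param node Child node name.
#' @param states Child's states, in order.
#' @param parents Character vector of parent node names.
#' @param parent_states Named list of parent state vectors, in order.
#' @param alpha Add-α pseudo-count applied to every cell (default 0:
#'   plain conditional relative frequencies).
#' @return A `bn_cpt` array (see [bn_cpt()]).
#' @export
fit_cpt <- function(cohort, node, states, parents, parent_states, alpha = 0) {
  stopifnot(alpha >= 0, length(parents) == length(parent_states))
  x <- cohort_column(cohort, node, states)
  if (length(x) == 0L) {
    stop("cannot estimate CPT for '", node, "' from an empty cohort",
         call. = FALSE)
  }
  for (p in parents) cohort_column(cohort, p, parent_states[[p]])
  configs <- expand.grid(parent_states, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  k <- length(states)
  vals <- matrix(NA_real_, nrow = k, ncol = max(nrow(configs), 1L))
  for (j in seq_len(max(nrow(configs), 1L))) {
    sel <- rep(TRUE, nrow(cohort))
    for (p in parents) sel <- sel & cohort[[p]] == configs[j, p]
    counts <- vapply(states, function(s) sum(sel & x == s), numeric(1)) + alpha
    vals[, j] <- if (sum(counts) > 0) counts / sum(counts) else rep(1 / k, k)
  }
  bn_cpt(node, states, vals, parents, parent_states)
}

#' Fit every CPT of a network structure from a discretized cohort
#'
#' Root nodes get relative-frequency priors ([fit_root_priors()]); child
#' nodes get conditional relative-frequency tables ([fit_cpt()]).
#'
#' @param cohort Discretized cohort data frame whose state columns match
#'   the node and state names of `spec`.
#' @param spec A `bn_spec`, e.g. [default_network_spec()].
#' @param alpha Add-α smoothing for child CPTs (default 0).
#' @return A `distress_bn`.
#' @examples
#' net <- fit_network(generate_fixture_cohort(), default_network_spec())
#' net
#' @export
fit_network <- function(cohort, spec, alpha = 0) {
  stopifnot(inherits(spec, "bn_spec"))
  cpts <- lapply(spec, function(nd) {
    if (length(nd$parents) == 0L) {
      bn_cpt(nd$name, nd$states,
             fit_root_priors(cohort, nd$name, nd$states))
    } else {
      fit_cpt(cohort, nd$name, nd$states, nd$parents,
              stats::setNames(lapply(spec[nd$parents], `[[`, "states"),
                              nd$parents),
              alpha = alpha)
    }
  })
  parameterized_network(spec, cpts)
}

cohort_column <- function(cohort, node, states) {
  if (!node %in% names(cohort)) {
    stop("cohort has no column for node '", node, "'", call. = FALSE)
  }
  x <- cohort[[node]]
  bad <- setdiff(unique(x), states)
  if (length(bad)) {
    stop("cohort column '", node, "' contains unknown state(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}
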