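# Factor algebra over named probability arrays.
#
# A factor is a numeric array whose dimnames are the state labels of its
# variables and whose dimname names are the variable names. A factor with
# all variables summed out or sliced away degenerates to a plain numeric
# scalar; callers accumulate those as constants.

f_vars <- function(f) names(dimnames(f))

f_states <- function(f) dimnames(f)

# Replicate a factor over additional variables and permute to `vars` order.
f_expand <- function(a, vars, states) {
  add <- setdiff(vars, f_vars(a))
  if (length(add)) {
    extra <- vapply(states[add], length, integer(1))
    v <- rep(as.vector(a), times = prod(extra))
    dim(v) <- c(dim(a), extra)
    dimnames(v) <- c(dimnames(a), states[add])
    a <- v
  }
  aperm(a, match(vars, f_vars(a)))
}

f_mul <- function(a, b) {
  if (is.null(a)) return(b)
  va <- f_vars(a)
  vb <- f_vars(b)
  vars <- union(va, vb)
  states <- c(f_states(a), f_states(b))
  states <- states[!duplicated(names(states))]
  f_expand(a, vars, states) * f_expand(b, vars, states)
}

# Sum a variable out of a factor; returns a scalar when it was the last one.
f_sumout <- function(a, var) {
  va <- f_vars(a)
  keep <- setdiff(va, var)
  if (length(keep) == 0L) return(sum(a))
  r <- apply(a, match(keep, va), sum)
  if (length(keep) == 1L) {
    r <- array(r, dim = length(r), dimnames = f_states(a)[keep])
  }
  r
}

# Slice a factor at var = state and drop that dimension.
f_reduce <- function(a, var, state) {
  va <- f_vars(a)
  i <- match(var, va)
  if (is.na(i)) return(a)
  args <- c(list(a), rep(list(TRUE), length(va)), list(drop = FALSE))
  args[[i + 1L]] <- state
  r <- do.call(`[`, args)
  nd <- dim(r)[-i]
  if (length(nd) == 0L) return(as.numeric(r))
  dn <- dimnames(r)[-i]
  dim(r) <- nd
  dimnames(r) <- dn
  r
}

# ---- relevance pruning ----------------------------------------------------

ancestors_of <- function(spec, nodes) {
  seen <- character(0)
  frontier <- nodes
  while (length(frontier)) {
    v <- frontier[[1L]]
    frontier <- frontier[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    frontier <- c(frontier, spec[[v]]$parents)
  }
  seen
}

# Nodes whose CPTs can influence P(query, evidence): the ancestral set of
# query+evidence, restricted to the moral-graph connected components that
# contain a query or evidence node. CPTs outside this set contribute a
# constant that cancels in the posterior, so dropping them also makes
# sensitivity derivatives of d-separated parameters exactly zero.
relevant_nodes <- function(spec, query, evidence_nodes) {
  anc <- ancestors_of(spec, unique(c(query, evidence_nodes)))
  adj <- stats::setNames(vector("list", length(anc)), anc)
  for (v in anc) {
    fam <- intersect(c(v, spec[[v]]$parents), anc)
    for (u in fam) adj[[u]] <- union(adj[[u]], setdiff(fam, u))
  }
  seen <- character(0)
  frontier <- intersect(unique(c(query, evidence_nodes)), anc)
  while (length(frontier)) {
    v <- frontier[[1L]]
    frontier <- frontier[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    frontier <- c(frontier, adj[[v]])
  }
  seen
}

# ---- variable elimination -------------------------------------------------

# Unnormalized joint P(query = ., evidence) by variable elimination with a
# min-degree elimination order over the pruned relevant subnetwork.
# Returns a 1-d factor over the states of `query` (which must not be an
# evidence node) scaled by P(evidence).
ve_query <- function(pnet, query, evidence = character()) {
  spec <- pnet$spec
  keep <- relevant_nodes(spec, query, names(evidence))
  factors <- list()
  const <- 1
  for (v in keep) {
    f <- pnet$cpts[[v]]
    class(f) <- "array"
    for (e in intersect(names(evidence), f_vars(f))) {
      f <- f_reduce(f, e, evidence[[e]])
      if (!is.array(f)) break
    }
    if (is.array(f)) factors[[length(factors) + 1L]] <- f else const <- const * f
  }
  to_eliminate <- setdiff(keep, c(query, names(evidence)))
  while (length(to_eliminate)) {
    v <- min_degree_pick(factors, to_eliminate)
    touch <- vapply(factors, function(f) v %in% f_vars(f), logical(1))
    if (!any(touch)) {
      to_eliminate <- setdiff(to_eliminate, v)
      next
    }
    prod <- Reduce(f_mul, factors[touch])
    r <- f_sumout(prod, v)
    factors <- factors[!touch]
    if (is.array(r)) factors[[length(factors) + 1L]] <- r else const <- const * r
    to_eliminate <- setdiff(to_eliminate, v)
  }
  out <- Reduce(f_mul, factors)
  if (is.null(out)) {
    out <- array(1, dim = length(spec[[query]]$states),
                 dimnames = stats::setNames(list(spec[[query]]$states), query))
  }
  out * const
}

# Min-degree heuristic: eliminate the variable with the fewest neighbours
# in the current factor-interaction graph. Correctness does not depend on
# the order, only cost.
min_degree_pick <- function(factors, candidates) {
  if (length(candidates) == 1L) return(candidates)
  scopes <- lapply(factors, f_vars)
  deg <- vapply(candidates, function(v) {
    nb <- unique(unlist(scopes[vapply(scopes, function(s) v %in% s, logical(1))]))
    length(setdiff(nb, v))
  }, integer(1))
  candidates[[which.min(deg)]]
}

#' Prior marginal distribution of every node
#'
#' Computes the marginal distribution of each node under no evidence by
#' exact variable elimination. This is the baseline ("reference point") of
#' the network before any evidence is introduced; for a root node it equals
#' the node's prior CPT.
#'
#' @param pnet A `distress_bn` from [parameterized_network()] or
#'   [fit_network()].
#' @return Named list: for each node, a named numeric probability vector
#'   over its states (each normalized).
#' @examples
#' net <- fit_network(generate_fixture_cohort(), default_network_spec())
#' round(prior_marginals(net)$physical_activity, 4)
#' @export
prior_marginals <- function(pnet) {
  stopifnot(inherits(pnet, "distress_bn"))
  posterior(pnet, evidence = character())
}

#' Exact posterior marginals given hard evidence
#'
#' Conditions the network on a set of hard observations and returns the
#' exact conditional marginal of every node, computed by variable
#' elimination. Evidence may be placed on any node, including the outcome
#' node — conditioning on the outcome and reading posteriors of its
#' ancestors is the diagnostic "backwards reasoning" direction.
#'
#' @param pnet A `distress_bn`.
#' @param evidence Named character vector of observed states (may be
#'   empty); see [as_evidence()].
#' @return Named list of named probability vectors, one per node. Evidence
#'   nodes carry a degenerate distribution (observed state = 1).
#' @examples
#' net <- fit_network(generate_fixture_cohort(), default_network_spec())
#' post <- posterior(net, c(psychological_distress = "severe"))
#' round(post$social_connectedness, 3)
#' @export
posterior <- function(pnet, evidence = character()) {
  stopifnot(inherits(pnet, "distress_bn"))
  evidence <- as_evidence(evidence, pnet$spec)
  nm <- node_names(pnet$spec)
  out <- stats::setNames(vector("list", length(nm)), nm)
  for (v in nm) {
    if (v %in% names(evidence)) {
      p <- stats::setNames(as.numeric(pnet$spec[[v]]$states == evidence[[v]]),
                           pnet$spec[[v]]$states)
      out[[v]] <- p
      next
    }
    f <- ve_query(pnet, v, evidence)
    z <- sum(f)
    if (z <= 0) {
      stop("evidence has probability zero under the model: ",
           paste(names(evidence), evidence, sep = "=", collapse = ", "),
           call. = FALSE)
    }
    out[[v]] <- stats::setNames(as.vector(f) / z, dimnames(f)[[1L]])
  }
  out
}

#' Joint probability of a full state assignment
#'
#' Evaluates the factored joint: the product over nodes of the CPT entry
#' for the node's assigned state given its parents' assigned states.
#'
#' @param pnet A `distress_bn`.
#' @param assignment Named character vector assigning a valid state to
#'   every node.
#' @return A single probability.
#' @export
joint_probability <- function(pnet, assignment) {
  stopifnot(inherits(pnet, "distress_bn"))
  nm <- node_names(pnet$spec)
  missing <- setdiff(nm, names(assignment))
  if (length(missing)) {
    stop("assignment is missing node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as_evidence(assignment[nm], pnet$spec)
  p <- 1
  for (v in nm) {
    fam <- c(v, pnet$spec[[v]]$parents)
    idx <- as.list(assignment[fam])
    p <- p * do.call(`[`, c(list(pnet$cpts[[v]]), idx))
  }
  as.numeric(p)
}

#' Posterior marginals by full joint enumeration (validation oracle)
#'
#' Computes the same quantities as [posterior()] by materializing the full
#' joint table and summing — no elimination, no pruning. Intended purely as
#' an independent cross-check of the variable-elimination engine on small
#' networks; refuses state spaces above `max_size` configurations.
#'
#' @param pnet A `distress_bn`.
#' @param evidence Named character vector of observed states (may be empty).
#' @param max_size Maximum number of joint configurations (default `1e7`).
#' @return Named list of named probability vectors, one per node, in the
#'   same layout as [posterior()].
#' @export
enumerate_posterior_oracle <- function(pnet, evidence = character(),
                                       max_size = 1e7) {
  stopifnot(inherits(pnet, "distress_bn"))
  evidence <- as_evidence(evidence, pnet$spec)
  spec <- pnet$spec
  nm <- node_names(spec)
  card <- vapply(spec, function(nd) length(nd$states), numeric(1))
  if (prod(card) > max_size) {
    stop("joint state space has ", format(prod(card)),
         " configurations; enumeration refused above ", format(max_size),
         call. = FALSE)
  }
  grid <- expand.grid(lapply(spec, `[[`, "states"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- rep(1, nrow(grid))
  for (v in nm) {
    fam <- c(v, spec[[v]]$parents)
    idx <- mapply(function(col, states) match(grid[[col]], states),
                  fam, lapply(spec[fam], `[[`, "states"), SIMPLIFY = FALSE)
    p <- p * pnet$cpts[[v]][do.call(cbind, idx)]
  }
  keep <- rep(TRUE, nrow(grid))
  for (e in names(evidence)) keep <- keep & grid[[e]] == evidence[[e]]
  z <- sum(p[keep])
  if (z <= 0) {
    stop("evidence has probability zero under the model", call. = FALSE)
  }
  out <- stats::setNames(vector("list", length(nm)), nm)
  for (v in nm) {
    states <- spec[[v]]$states
    probs <- vapply(states, function(s) sum(p[keep & grid[[v]] == s]) / z,
                    numeric(1))
    out[[v]] <- stats::setNames(probs, states)
  }
  out
}
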