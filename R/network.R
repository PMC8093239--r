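#' Define a categorical network node
#'
#' A node in a discrete Bayesian network: a named categorical variable with
#' an ordered set of states and an ordered set of parent nodes.
#'
#' @param name Node name (single non-empty string).
#' @param states Character vector of at least two unique state labels,
#'   in display order.
#' @param parents Character vector of parent node names (default none).
#' @return An object of class `bn_node`.
#' @examples
#' bn_node("sleep", c("good", "poor"))
#' bn_node("qol_physical", c("low", "high"),
#'         parents = c("eating_behaviours", "physical_activity", "sleep"))
#' @export
bn_node <- function(name, states, parents = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  states <- as.character(states)
  if (length(states) < 2L) {
    stop("node '", name, "': at least two states are required", call. = FALSE)
  }
  if (anyDuplicated(states)) {
    stop("node '", name, "': state labels must be unique", call. = FALSE)
  }
  parents <- as.character(parents)
  if (anyDuplicated(parents)) {
    stop("node '", name, "': parent names must be unique", call. = FALSE)
  }
  if (name %in% parents) {
    stop("node '", name, "' cannot be its own parent", call. = FALSE)
  }
  structure(list(name = name, states = states, parents = parents),
            class = "bn_node")
}

#' Assemble a network structure from node definitions
#'
#' Collects [bn_node()] definitions into a directed-graph specification and
#' checks referential integrity: node names are unique and every parent
#' reference resolves. Acyclicity is checked by [validate_network()].
#'
#' @param nodes A list of `bn_node` objects.
#' @return An object of class `bn_spec`: a list of nodes keyed by name.
#' @seealso [validate_network()], [default_network_spec()]
#' @export
bn_spec <- function(nodes) {
  stopifnot(is.list(nodes), length(nodes) > 0L)
  ok <- vapply(nodes, inherits, logical(1), what = "bn_node")
  if (!all(ok)) stop("all elements must be bn_node objects", call. = FALSE)
  nm <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate node names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(nodes) <- nm
  for (nd in nodes) {
    bad <- setdiff(nd$parents, nm)
    if (length(bad)) {
      stop("node '", nd$name, "' references unknown parent(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(nodes, class = "bn_spec")
}

node_names <- function(spec) vapply(spec, `[[`, character(1), "name")

#' Validate a network structure and return a topological order
#'
#' Verifies that the directed graph encoded by a `bn_spec` is acyclic.
#' Uses Kahn's algorithm; on failure the error message names one directed
#' cycle so the offending arcs can be located.
#'
#' @param spec A `bn_spec`.
#' @return Character vector of node names in which every parent precedes
#'   all of its children.
#' @examples
#' s <- bn_spec(list(bn_node("a", c("x", "y")),
#'                   bn_node("b", c("x", "y"), parents = "a")))
#' validate_network(s)
#' @export
validate_network <- function(spec) {
  stopifnot(inherits(spec, "bn_spec"))
  nm <- node_names(spec)
  indeg <- vapply(spec, function(nd) length(nd$parents), integer(1))
  children <- lapply(nm, function(p) {
    nm[vapply(spec, function(nd) p %in% nd$parents, logical(1))]
  })
  names(children) <- nm
  order <- character(0)
  ready <- nm[indeg == 0L]
  while (length(ready)) {
    v <- ready[[1L]]
    ready <- ready[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order) < length(nm)) {
    cyc <- find_cycle(spec, setdiff(nm, order))
    stop("network contains a directed cycle: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  order
}

# Walk parent links among the unresolved nodes until one repeats.
find_cycle <- function(spec, remaining) {
  v <- remaining[[1L]]
  path <- character(0)
  while (!(v %in% path)) {
    path <- c(path, v)
    v <- intersect(spec[[v]]$parents, remaining)[[1L]]
  }
  i <- match(v, path)
  c(path[seq(i, length(path))], v)
}

#' Construct a conditional probability table
#'
#' Builds the CPT of one node as a probability array whose first dimension
#' indexes the node's own states and whose remaining dimensions index the
#' states of its parents, in parent order. Every column (one per full
#' parent-state configuration) must be a probability vector.
#'
#' @param node Node name.
#' @param states Character vector of the node's states.
#' @param values Numeric array of probabilities with
#'   `dim = c(length(states), <parent cardinalities>)`. A plain vector is
#'   accepted for a parentless node.
#' @param parents Character vector of parent names (default none).
#' @param parent_states Named list of state vectors, one per parent.
#' @return A probability array of class `bn_cpt` with named `dimnames`.
#' @examples
#' # P(b | a): rows are b's states, column per state of a
#' bn_cpt("b", c("b1", "b2"), matrix(c(0.8, 0.2, 0.2, 0.8), nrow = 2),
#'        parents = "a", parent_states = list(a = c("a1", "a2")))
#' @export
bn_cpt <- function(node, states, values, parents = character(),
                   parent_states = list()) {
  stopifnot(length(parents) == length(parent_states))
  dims <- c(length(states), vapply(parent_states, length, integer(1)))
  values <- as.numeric(values)
  if (length(values) != prod(dims)) {
    stop("CPT for '", node, "': expected ", prod(dims),
         " probabilities, got ", length(values), call. = FALSE)
  }
  a <- array(values, dim = dims,
             dimnames = stats::setNames(c(list(states), parent_states),
                                        c(node, parents)))
  check_cpt(a, node)
  class(a) <- c("bn_cpt", class(a))
  a
}

# CPT invariants: probabilities in [0,1]; every parent-configuration
# column sums to 1 within 1e-9.
check_cpt <- function(a, node) {
  if (any(a < -1e-12) || any(a > 1 + 1e-12)) {
    stop("CPT for '", node, "': probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  sums <- if (length(dim(a)) == 1L) sum(a) else apply(a, seq_along(dim(a))[-1L], sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("CPT for '", node, "': each conditional distribution must sum to 1 ",
         "(max deviation ", format(max(abs(sums - 1))), ")", call. = FALSE)
  }
  invisible(a)
}

#' Combine a structure and CPTs into a parameterized network
#'
#' The full model object: a validated DAG plus one CPT per node, with CPT
#' dimensions checked against the structure. All inference, scenario and
#' sensitivity functions operate on this object.
#'
#' @param spec A `bn_spec`.
#' @param cpts Named list of `bn_cpt` arrays, one per node.
#' @return An object of class `distress_bn` with elements `spec`, `cpts`
#'   and `order` (a topological node order).
#' @seealso [fit_network()], [prior_marginals()], [posterior()]
#' @export
parameterized_network <- function(spec, cpts) {
  order <- validate_network(spec)
  nm <- node_names(spec)
  missing <- setdiff(nm, names(cpts))
  if (length(missing)) {
    stop("missing CPT for node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (v in nm) {
    nd <- spec[[v]]
    a <- cpts[[v]]
    want <- stats::setNames(
      c(list(nd$states), lapply(spec[nd$parents], `[[`, "states")),
      c(v, nd$parents))
    have <- dimnames(a)
    if (!identical(lapply(want, as.character), lapply(have, as.character)) ||
        !identical(names(want), names(have))) {
      stop("CPT for '", v, "' does not match the node's states/parents",
           call. = FALSE)
    }
    check_cpt(a, v)
  }
  structure(list(spec = spec, cpts = cpts[nm], order = order),
            class = "distress_bn")
}

#' @export
print.distress_bn <- function(x, ...) {
  nm <- node_names(x$spec)
  n_par <- vapply(x$spec, function(nd) length(nd$parents), integer(1))
  cat("Discrete Bayesian network:", length(nm), "nodes,",
      sum(n_par), "arcs\n")
  cat("  roots:", paste(nm[n_par == 0L], collapse = ", "), "\n")
  n_param <- sum(vapply(x$cpts, length, integer(1)))
  cat("  free CPT entries:", n_param, "\n")
  invisible(x)
}

#' Validate hard evidence against a network structure
#'
#' Evidence is a set of hard observations: a named character vector mapping
#' node names to observed states ("instantiation" of nodes). Scenario
#' analyses condition the network on such evidence, including on the
#' outcome node for diagnostic ("backwards") reasoning.
#'
#' @param evidence Named character vector, e.g.
#'   `c(psychological_distress = "severe")`. May be empty.
#' @param spec A `bn_spec`.
#' @return The evidence, validated.
#' @export
as_evidence <- function(evidence, spec) {
  if (length(evidence) == 0L) return(stats::setNames(character(0), character(0)))
  evidence <- unlist(evidence)
  nms <- names(evidence)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("evidence must be a named character vector (node = state)",
         call. = FALSE)
  }
  if (anyDuplicated(nms)) {
    stop("evidence lists node(s) more than once: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(nms, node_names(spec))
  if (length(bad)) {
    stop("evidence on unknown node(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (v in nms) {
    if (!(evidence[[v]] %in% spec[[v]]$states)) {
      stop("'", evidence[[v]], "' is not a state of node '", v, "' (states: ",
           paste(spec[[v]]$states, collapse = ", "), ")", call. = FALSE)
    }
  }
  evidence
}
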