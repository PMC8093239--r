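# Shared builders for the test suite: hand-sized analytic networks and a
# seeded random-network generator for property tests.

# Two-node network a -> b with adjustable parameters; the Bayes-rule
# posteriors are computable by hand.
hand_ab_network <- function(p_a1 = 0.5, p_b1_a1 = 0.8, p_b1_a0 = 0.2) {
  spec <- bn_spec(list(
    bn_node("a", c("a1", "a0")),
    bn_node("b", c("b1", "b0"), parents = "a")))
  cpts <- list(
    a = bn_cpt("a", c("a1", "a0"), c(p_a1, 1 - p_a1)),
    b = bn_cpt("b", c("b1", "b0"),
               c(p_b1_a1, 1 - p_b1_a1, p_b1_a0, 1 - p_b1_a0),
               parents = "a", parent_states = list(a = c("a1", "a0"))))
  parameterized_network(spec, cpts)
}

# Random network with bounded joint-state-space size; CPT rows are
# Dirichlet-ish draws bounded away from zero.
rand_network <- function(seed, n_nodes = NULL, max_nodes = 12, max_states = 4,
                         max_parents = 3, max_joint = 20000) {
  set.seed(seed)
  repeat {
    n <- if (is.null(n_nodes)) sample(3:max_nodes, 1) else n_nodes
    card <- sample(2:max_states, n, replace = TRUE)
    if (prod(card) <= max_joint) break
  }
  nms <- sprintf("v%02d", seq_len(n))
  nodes <- vector("list", n)
  for (i in seq_len(n)) {
    np <- if (i == 1) 0L else sample(0:min(max_parents, i - 1L), 1)
    parents <- if (np > 0) sample(nms[seq_len(i - 1L)], np) else character()
    nodes[[i]] <- bn_node(nms[i], paste0("s", seq_len(card[i])), parents)
  }
  spec <- bn_spec(nodes)
  cpts <- lapply(spec, function(nd) {
    k <- length(nd$states)
    pstates <- stats::setNames(lapply(spec[nd$parents], `[[`, "states"),
                               nd$parents)
    ncfg <- prod(vapply(pstates, length, integer(1)))
    vals <- matrix(stats::rgamma(k * max(ncfg, 1L), 1) + 0.05, nrow = k)
    vals <- sweep(vals, 2, colSums(vals), "/")
    bn_cpt(nd$name, nd$states, vals, nd$parents, pstates)
  })
  parameterized_network(spec, cpts)
}

# Fixed 5-node network used by the parameter-recovery experiments.
recovery_network <- function() {
  spec <- bn_spec(list(
    bn_node("a", c("a1", "a2")),
    bn_node("b", c("b1", "b2", "b3"), parents = "a"),
    bn_node("c", c("c1", "c2"), parents = "a"),
    bn_node("d", c("d1", "d2"), parents = c("b", "c")),
    bn_node("e", c("e1", "e2"), parents = "d")))
  cpts <- list(
    a = bn_cpt("a", c("a1", "a2"), c(0.3, 0.7)),
    b = bn_cpt("b", c("b1", "b2", "b3"),
               c(0.5, 0.3, 0.2, 0.1, 0.6, 0.3),
               parents = "a", parent_states = list(a = c("a1", "a2"))),
    c = bn_cpt("c", c("c1", "c2"), c(0.8, 0.2, 0.35, 0.65),
               parents = "a", parent_states = list(a = c("a1", "a2"))),
    d = bn_cpt("d", c("d1", "d2"),
               c(0.9, 0.1, 0.4, 0.6, 0.25, 0.75,
                 0.55, 0.45, 0.7, 0.3, 0.15, 0.85),
               parents = c("b", "c"),
               parent_states = list(b = c("b1", "b2", "b3"),
                                    c = c("c1", "c2"))),
    e = bn_cpt("e", c("e1", "e2"), c(0.6, 0.4, 0.2, 0.8),
               parents = "d", parent_states = list(d = c("d1", "d2"))))
  parameterized_network(spec, cpts)
}

# Descendant set of a node (for d-separation checks on random DAGs).
descendants_of <- function(spec, node) {
  nms <- vapply(spec, `[[`, character(1), "name")
  children <- function(v) {
    nms[vapply(spec, function(nd) v %in% nd$parents, logical(1))]
  }
  seen <- character(0)
  frontier <- children(node)
  while (length(frontier)) {
    v <- frontier[[1L]]
    frontier <- frontier[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    frontier <- c(frontier, children(v))
  }
  seen
}

# Total-variation distance between two probability vectors.
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))
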