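# Finite-difference oracle used to cross-check the analytic sensitivity
# derivatives: perturbs one CPT entry with proportional covariation of its
# complements (an independent re-implementation sharing nothing with the
# engine's linear-coefficient route) and differentiates the posterior
# centrally.

# Column index of a parent configuration in the native
# first-parent-fastest layout.
cfg_index <- function(spec, node, cfg) {
  parents <- spec[[node]]$parents
  card <- vapply(spec[parents], function(x) length(x$states), integer(1))
  idx <- vapply(parents, function(p) match(cfg[[p]], spec[[p]]$states),
                integer(1))
  as.integer(1 + sum((idx - 1) * cumprod(c(1, card[-length(card)]))))
}

fd_derivative <- function(pnet, node, cfg, state, target, tstate,
                          evidence = character(), h = 1e-4) {
  cpt_matrix <- function() {
    k <- length(pnet$spec[[node]]$states)
    matrix(as.numeric(pnet$cpts[[node]]), nrow = k,
           dimnames = list(pnet$spec[[node]]$states, NULL))
  }
  j <- if (length(cfg)) cfg_index(pnet$spec, node, cfg) else 1L
  eval_at <- function(t) {
    m <- cpt_matrix()
    col <- m[, j]
    old <- col[[state]]
    rest <- setdiff(rownames(m), state)
    col[rest] <- if (old < 1) col[rest] * (1 - t) / (1 - old)
                 else rep((1 - t) / length(rest), length(rest))
    col[[state]] <- t
    m[, j] <- col
    p2 <- pnet
    a <- pnet$cpts[[node]]
    a[] <- m
    p2$cpts[[node]] <- a
    posterior(p2, evidence)[[target]][[tstate]]
  }
  theta <- cpt_matrix()[state, j]
  (eval_at(theta + h) - eval_at(theta - h)) / (2 * h)
}
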