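test_that("validate_network orders parents before children and names cycles", {
  chain <- bn_spec(list(
    bn_node("A", c("x", "y")),
    bn_node("B", c("x", "y"), parents = "A"),
    bn_node("C", c("x", "y"), parents = "B")))
  expect_identical(validate_network(chain), c("A", "B", "C"))

  single <- bn_spec(list(bn_node("only", c("x", "y"))))
  expect_identical(validate_network(single), "only")

  cyc <- bn_spec(list(
    bn_node("A", c("x", "y"), parents = "B"),
    bn_node("B", c("x", "y"), parents = "A")))
  expect_error(validate_network(cyc), "cycle.*A|cycle.*B")

  expect_error(
    bn_spec(list(bn_node("A", c("x", "y"), parents = "ghost"))),
    "unknown parent.*ghost")
})

test_that("node and CPT invariants are enforced", {
  expect_error(bn_node("a", "one_state"), "at least two states")
  expect_error(bn_node("a", c("x", "x")), "unique")
  expect_error(bn_node("a", c("x", "y"), parents = "a"), "own parent")
  expect_error(bn_cpt("a", c("x", "y"), c(0.5, 0.4)), "sum to 1")
  expect_error(bn_cpt("a", c("x", "y"), c(1.2, -0.2)), "\\[0, 1\\]")
  # one entry per parent configuration, no omissions
  expect_error(
    bn_cpt("b", c("x", "y"), c(0.5, 0.5), parents = "a",
           parent_states = list(a = c("x", "y"))),
    "expected 4 probabilities")
})

test_that("joint_probability multiplies CPT entries along the assignment", {
  ind <- parameterized_network(
    bn_spec(list(bn_node("a", c("a1", "a0")), bn_node("b", c("b1", "b0")))),
    list(a = bn_cpt("a", c("a1", "a0"), c(0.5, 0.5)),
         b = bn_cpt("b", c("b1", "b0"), c(0.5, 0.5))))
  expect_equal(joint_probability(ind, c(a = "a1", b = "b0")), 0.25)

  net <- hand_ab_network()
  expect_equal(joint_probability(net, c(a = "a1", b = "b1")), 0.40)

  zero <- hand_ab_network(p_b1_a1 = 0)
  expect_identical(joint_probability(zero, c(a = "a1", b = "b1")), 0)

  expect_error(joint_probability(net, c(a = "a1")), "missing node")
})

test_that("prior marginals: roots keep their priors, children marginalize", {
  net <- hand_ab_network(p_a1 = 0.11)
  pm <- prior_marginals(net)
  expect_equal(unname(pm$a), c(0.11, 0.89), tolerance = 1e-12)

  # P(b1) = 0.5*0.8 + 0.5*0.2 = 0.5 (full enumeration by hand)
  pm2 <- prior_marginals(hand_ab_network())
  expect_equal(unname(pm2$b), c(0.5, 0.5), tolerance = 1e-12)

  # deterministic identity channel copies the parent marginal
  copy <- hand_ab_network(p_a1 = 0.3, p_b1_a1 = 1, p_b1_a0 = 0)
  pm3 <- prior_marginals(copy)
  expect_equal(unname(pm3$b), unname(pm3$a), tolerance = 1e-12)
})

test_that("posterior conditions exactly, in both causal and diagnostic direction", {
  net <- hand_ab_network()
  post <- posterior(net, c(b = "b1"))
  # Bayes' rule by hand: P(a1 | b1) = 0.4 / 0.5 = 0.8
  expect_equal(post$a[["a1"]], 0.8, tolerance = 1e-12)
  expect_equal(unname(post$b), c(1, 0))

  # evidence on a node makes its own distribution degenerate
  post2 <- posterior(net, c(a = "a0"))
  expect_identical(unname(post2$a), c(0, 1))

  # zero-probability evidence errors instead of returning NaN
  impossible <- hand_ab_network(p_b1_a1 = 0, p_b1_a0 = 0)
  expect_error(posterior(impossible, c(b = "b1")), "probability zero")
})

test_that("evidence validation rejects malformed observations", {
  net <- hand_ab_network()
  expect_error(posterior(net, c(z = "b1")), "unknown node")
  expect_error(posterior(net, c(b = "nope")), "not a state")
  expect_error(posterior(net, c(b = "b1", b = "b0")), "more than once")
})

test_that("variable elimination matches the enumeration oracle on random networks", {
  for (seed in 1:100) {
    net <- rand_network(seed)
    nms <- names(net$spec)
    # evidence on a random subset (possibly empty)
    set.seed(seed + 5000)
    n_ev <- sample(0:2, 1)
    ev <- character(0)
    if (n_ev > 0) {
      ev_nodes <- sample(nms, n_ev)
      ev <- vapply(ev_nodes, function(v) sample(net$spec[[v]]$states, 1),
                   character(1))
    }
    ve <- tryCatch(posterior(net, ev), error = function(e) e)
    or <- tryCatch(enumerate_posterior_oracle(net, ev), error = function(e) e)
    if (inherits(ve, "error") || inherits(or, "error")) {
      # both routes must agree that the evidence is impossible
      expect_true(inherits(ve, "error") && inherits(or, "error"))
      next
    }
    for (v in nms) {
      expect_equal(ve[[v]], or[[v]], tolerance = 1e-9,
                   label = sprintf("seed %d node %s", seed, v))
    }
  }
})

test_that("the enumeration oracle refuses oversized state spaces", {
  net <- rand_network(7)
  expect_error(enumerate_posterior_oracle(net, max_size = 2),
               "enumeration refused")
  expect_equal(enumerate_posterior_oracle(net), prior_marginals(net),
               tolerance = 1e-9)
})

test_that("root evidence leaves d-separated (non-descendant) nodes unchanged", {
  for (seed in 1:25) {
    net <- rand_network(seed + 300)
    nms <- names(net$spec)
    roots <- nms[vapply(net$spec, function(nd) length(nd$parents) == 0L,
                        logical(1))]
    set.seed(seed)
    ev_roots <- sample(roots, min(2, length(roots)))
    ev <- vapply(ev_roots, function(v) sample(net$spec[[v]]$states, 1),
                 character(1))
    base <- prior_marginals(net)
    post <- posterior(net, ev)
    desc <- unique(unlist(lapply(ev_roots, descendants_of,
                                 spec = net$spec)))
    untouched <- setdiff(nms, c(ev_roots, desc))
    for (v in untouched) {
      expect_lt(max(abs(post[[v]] - base[[v]])), 1e-12)
    }
  }
})

test_that("all returned distributions are normalized", {
  for (seed in c(11, 42, 99)) {
    net <- rand_network(seed)
    for (p in posterior(net, character(0))) {
      expect_lt(abs(sum(p) - 1), 1e-9)
      expect_true(all(p >= 0 & p <= 1 + 1e-12))
    }
  }
})

test_that("chained conditioning is consistent with the joint", {
  for (seed in c(3, 17, 58)) {
    net <- rand_network(seed)
    nms <- names(net$spec)
    set.seed(seed)
    ab <- sample(nms, 2)
    a_state <- sample(net$spec[[ab[1]]]$states, 1)
    b_state <- sample(net$spec[[ab[2]]]$states, 1)
    # P(A=a, B=b) from the enumeration of the joint
    oracle_joint <- 0
    grid <- expand.grid(lapply(net$spec, `[[`, "states"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keep <- grid[[ab[1]]] == a_state & grid[[ab[2]]] == b_state
    for (i in which(keep)) {
      oracle_joint <- oracle_joint +
        joint_probability(net, unlist(grid[i, , drop = TRUE]))
    }
    # P(A=a) * P(B=b | A=a) from two inference calls
    p_a <- prior_marginals(net)[[ab[1]]][[a_state]]
    p_b_a <- posterior(net, stats::setNames(a_state, ab[1]))[[ab[2]]][[b_state]]
    expect_equal(oracle_joint, p_a * p_b_a, tolerance = 1e-9)
  }
})
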