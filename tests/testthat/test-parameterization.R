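test_that("K10 banding follows the established screening cutoffs", {
  expect_identical(k10_band(15), "well")
  expect_identical(k10_band(22), "mild")
  expect_identical(k10_band(27), "moderate")
  expect_identical(k10_band(30), "severe")
  # boundary scores: 19 is still well, 20 opens the mild band,
  # 24/25 and 29/30 are the other band edges
  expect_identical(k10_band(c(19, 20, 24, 25, 29, 50)),
                   c("well", "mild", "mild", "moderate", "moderate",
                     "severe"))
  expect_error(k10_band(9), "out of range")
  expect_error(k10_band(51), "out of range")
})

test_that("PSQI banding treats 5 as the last good-sleep score", {
  expect_identical(psqi_band(c(0, 5, 6, 21)),
                   c("good", "good", "poor", "poor"))
  expect_error(psqi_band(22), "out of range")
})

test_that("midpoint banding splits the theoretical range, boundary upward", {
  expect_identical(midpoint_band(52, 15, 75), "high")
  expect_identical(midpoint_band(45, 15, 75), "high")  # midpoint inclusive
  expect_identical(midpoint_band(44, 15, 75), "low")
  expect_identical(midpoint_band(18, 3, 21, labels = c("less", "more")),
                   "more")
  expect_error(midpoint_band(80, 15, 75), "out of range")
})

test_that("default rules partition each score range totally and deterministically", {
  rules <- default_discretization_rules()
  expect_setequal(names(rules), names(default_network_spec()))
  for (r in rules) {
    if (r$kind == "passthrough") next
    grid <- seq(r$scale_min, r$scale_max, by = 0.5)
    s1 <- distressbn:::apply_rule(r, grid)
    s2 <- distressbn:::apply_rule(r, grid)
    expect_identical(s1, s2)
    expect_false(anyNA(s1))
    # every in-range score maps to exactly one declared state
    states <- if (r$kind == "midpoint") r$labels else r$states
    expect_true(all(s1 %in% states))
  }
})

test_that("discretizing the raw fixture reproduces the reference counts", {
  raw <- fixture_raw_cohort()
  coh <- discretize_cohort(raw, default_discretization_rules())
  expect_identical(nrow(coh), 64L)
  for (v in names(reference_cohort_counts())) {
    want <- reference_cohort_counts()[[v]]
    got <- table(factor(coh[[v]], levels = names(want)))
    expect_identical(as.integer(got), as.integer(want), label = v)
  }
})

test_that("discretize_cohort is complete-case with a logged drop count", {
  raw <- fixture_raw_cohort()
  raw$k10_total[3] <- NA
  expect_message(
    coh <- discretize_cohort(raw, default_discretization_rules()),
    "dropped 1 record")
  expect_identical(nrow(coh), 63L)
  expect_identical(attr(coh, "n_dropped"), 1L)
  expect_false("P003" %in% coh$participant_id)

  empty <- raw[0, ]
  expect_identical(nrow(discretize_cohort(empty,
                                          default_discretization_rules())),
                   0L)
})

test_that("root priors are relative frequencies summing to one", {
  coh <- generate_fixture_cohort()
  pa <- fit_root_priors(coh, "physical_activity", c("less", "more"))
  expect_equal(unname(pa), c(7, 57) / 64, tolerance = 1e-15)
  expect_identical(sum(pa), 1)

  one_state <- data.frame(participant_id = "x",
                          sleep = rep("good", 5))
  expect_equal(unname(fit_root_priors(one_state, "sleep",
                                      c("good", "poor"))),
               c(1, 0))

  half <- data.frame(cyberstrife = rep(c("no", "yes"), each = 32))
  expect_equal(unname(fit_root_priors(half, "cyberstrife", c("no", "yes"))),
               c(0.5, 0.5))

  expect_error(fit_root_priors(coh[0, ], "sleep", c("good", "poor")),
               "empty cohort")
})

test_that("fit_cpt estimates conditional relative frequencies", {
  # child deterministically copies its parent
  coh <- data.frame(a = rep(c("a1", "a0"), c(10, 6)),
                    b = rep(c("b1", "b0"), c(10, 6)))
  cpt <- fit_cpt(coh, "b", c("b1", "b0"), "a",
                 list(a = c("a1", "a0")))
  expect_equal(as.numeric(cpt[, "a1"]), c(1, 0))
  expect_equal(as.numeric(cpt[, "a0"]), c(0, 1))

  # 8 of 10 b1 given a1
  coh2 <- data.frame(a = c(rep("a1", 10), rep("a0", 4)),
                     b = c(rep("b1", 8), rep("b0", 2), rep("b1", 2),
                           rep("b0", 2)))
  cpt2 <- fit_cpt(coh2, "b", c("b1", "b0"), "a", list(a = c("a1", "a0")))
  expect_equal(cpt2[["b1", "a1"]], 0.8)

  # an unobserved parent configuration gets the uniform row
  coh3 <- data.frame(a = rep("a1", 5), b = rep("b1", 5))
  cpt3 <- fit_cpt(coh3, "b", c("b1", "b0"), "a", list(a = c("a1", "a0")))
  expect_equal(as.numeric(cpt3[, "a0"]), c(0.5, 0.5))

  # optional add-alpha smoothing shrinks observed rows toward uniform
  cpt4 <- fit_cpt(coh3, "b", c("b1", "b0"), "a", list(a = c("a1", "a0")),
                  alpha = 1)
  expect_equal(as.numeric(cpt4[, "a1"]), c(6, 1) / 7)
})

test_that("fit_network reproduces reference marginals and handles tiny cohorts", {
  coh <- generate_fixture_cohort()
  net <- fit_network(coh, default_network_spec())
  counts <- reference_cohort_counts()
  roots <- names(net$spec)[vapply(net$spec,
                                  function(nd) length(nd$parents) == 0L,
                                  logical(1))]
  for (v in roots) {
    expect_equal(unname(prior_marginals(net)[[v]]),
                 unname(counts[[v]] / 64), tolerance = 1e-12, label = v)
  }

  one <- coh[1, ]
  net1 <- fit_network(one, default_network_spec())
  # observed rows degenerate, unobserved uniform
  s1 <- one$sleep
  expect_equal(net1$cpts$sleep[[s1]], 1)
  cyb <- net1$cpts$cyberstrife
  observed_cfg <- one$social_connectedness
  other_cfg <- setdiff(c("low", "high"), observed_cfg)
  expect_equal(cyb[[one$cyberstrife, observed_cfg]], 1)
  expect_equal(as.numeric(cyb[, other_cfg]), c(0.5, 0.5))
})

test_that("CPTs are recovered from 50k ancestral samples within TV 0.02", {
  truth <- recovery_network()
  samp <- sample_from_network(truth, 50000, seed = 2024)
  refit <- fit_network(samp, truth$spec)
  for (v in names(truth$spec)) {
    a <- truth$cpts[[v]]
    b <- refit$cpts[[v]]
    k <- length(truth$spec[[v]]$states)
    ma <- matrix(as.numeric(a), nrow = k)
    mb <- matrix(as.numeric(b), nrow = k)
    for (j in seq_len(ncol(ma))) {
      expect_lt(tv_dist(ma[, j], mb[, j]), 0.02)
    }
  }
})
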