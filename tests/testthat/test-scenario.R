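test_that("percent_change reproduces published worked values", {
  expect_equal(percent_change(3, 21), 600)
  expect_equal(percent_change(2, 33), 1550)
  expect_equal(percent_change(2, 19), 850)
  expect_equal(percent_change(34, 43), (43 - 34) / 34 * 100)
  expect_equal(round_half_away(percent_change(34, 43)), 26)
  for (p in c(0.01, 0.2, 37, 99)) expect_equal(percent_change(p, p), 0)
  expect_error(percent_change(0, 5), "undefined")
  expect_error(percent_change(-1, 5), "non-negative")
})

test_that("percent_change is sign-antisymmetric around the baseline", {
  set.seed(1)
  for (i in 1:50) {
    a <- runif(1, 0.01, 1)
    b <- runif(1, 0, 2 * a)
    expect_equal(percent_change(a, b), -percent_change(a, 2 * a - b),
                 tolerance = 1e-10)
  }
})

test_that("half-away-from-zero rounding differs from banker's rounding where it must", {
  expect_identical(round_half_away(c(-26.5, -0.5, 0.5, 2.5)),
                   c(-27, -1, 1, 3))
  expect_identical(round_half_away(c(-1.2, 1.2)), c(-1, 1))
})

test_that("run_scenario matches hand Bayes computation on a two-node network", {
  net <- hand_ab_network()
  res <- run_scenario(net, scenario("diagnostic", c(b = "b1")))
  a1 <- res[res$node == "a" & res$state == "a1", ]
  # baseline P(a1)=0.5, posterior 0.8 -> +60%
  expect_equal(a1$baseline, 0.5, tolerance = 1e-12)
  expect_equal(a1$scenario, 0.8, tolerance = 1e-12)
  expect_equal(a1$delta_pct, 60, tolerance = 1e-9)
  expect_false(a1$instantiated)
  expect_true(all(res$instantiated[res$node == "b"]))
  expect_equal(res$scenario[res$node == "b" & res$state == "b1"], 1)
})

test_that("evidence on a childless root changes nothing else", {
  spec <- bn_spec(list(
    bn_node("iso", c("u", "v")),
    bn_node("a", c("a1", "a0")),
    bn_node("b", c("b1", "b0"), parents = "a")))
  net <- parameterized_network(spec, list(
    iso = bn_cpt("iso", c("u", "v"), c(0.4, 0.6)),
    a = bn_cpt("a", c("a1", "a0"), c(0.5, 0.5)),
    b = bn_cpt("b", c("b1", "b0"), c(0.8, 0.2, 0.2, 0.8),
               parents = "a", parent_states = list(a = c("a1", "a0")))))
  res <- run_scenario(net, scenario("isolated", c(iso = "u")))
  free <- res[!res$instantiated, ]
  expect_true(all(abs(free$delta_pct) < 1e-12))
  expect_identical(affected_nodes(res), character(0))
})

test_that("affected_nodes lists exactly the reachable nodes", {
  coh <- generate_fixture_cohort()
  net <- fit_network(coh, default_network_spec())

  res_sc <- run_scenario(net, preset_scenarios()$low_social_connectedness)
  expect_setequal(affected_nodes(res_sc, tolerance = 1e-9),
                  c("cyberstrife", "qol_social", "psychological_distress"))

  res_eat <- run_scenario(net, preset_scenarios()$unhealthy_eating)
  expect_setequal(affected_nodes(res_eat, tolerance = 1e-9),
                  c("qol_physical", "psychological_distress"))

  # conditioning the outcome node reaches every ancestor (backwards
  # reasoning) plus the ancestors' other descendants; sleep and physical
  # activity are d-separated from the outcome by the collider at
  # qol_physical and must not move
  res_sev <- run_scenario(net, preset_scenarios()$severe_distress)
  expect_setequal(affected_nodes(res_sev, tolerance = 1e-9),
                  setdiff(names(net$spec),
                          c("psychological_distress", "sleep",
                            "physical_activity")))
  ancestors <- c("eating_behaviours", "social_connectedness", "qol_psych",
                 "metacognition", "impulsivity", "mindfulness")
  expect_true(all(ancestors %in% affected_nodes(res_sev, tolerance = 1e-9)))

  expect_identical(affected_nodes(res_sev, tolerance = 1e12), character(0))
})

test_that("report layer reproduces the printed change cells of the scenario tables", {
  # (baseline %, scenario %) -> printed change, from the two published
  # single-evidence scenario tables
  cells <- rbind(
    c(2, 33, 1550), c(98, 67, -32),            # QOL physical low/high
    c(83, 61, -27), c(11, 12, 9),              # distress well/mild
    c(3, 21, 600), c(2, 6, 200),               # distress moderate/severe
    c(2, 19, 850), c(98, 81, -17),             # QOL social low/high
    c(66, 57, -14), c(34, 43, 26),             # cyberstrife no/yes
    c(83, 74, -11), c(11, 13, 18),             # distress well/mild
    c(3, 7, 133))                              # distress moderate
  fake <- data.frame(node = "n", state = paste0("s", seq_len(nrow(cells))),
                     baseline = cells[, 1] / 100,
                     scenario = cells[, 2] / 100,
                     delta_pct = NA_real_, instantiated = FALSE,
                     stringsAsFactors = FALSE)
  class(fake) <- c("scenario_result", class(fake))
  attr(fake, "scenario_name") <- "printed-cells check"
  attr(fake, "evidence") <- character(0)
  out <- render_scenario_table(fake)
  expect_identical(out$baseline_pct, cells[, 1])
  expect_identical(out$scenario_pct, cells[, 2])
  expect_identical(out$delta_pct, cells[, 3])
})

test_that("render keeps the exact statistic and marks undefined baselines", {
  net <- hand_ab_network(p_a1 = 0.004)  # rounds to 0%
  res <- run_scenario(net, scenario("s", c(b = "b1")))
  out <- render_scenario_table(res)
  a1 <- out[out$node == "a" & out$state == "a1", ]
  expect_identical(a1$baseline_pct, 0)
  expect_true(is.na(a1$delta_pct))
  expect_false(is.na(a1$delta_pct_exact))
  # unrounded statistic preserved alongside
  raw <- res[res$node == "a" & res$state == "a1", ]
  expect_equal(a1$delta_pct_exact, raw$delta_pct)
})
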