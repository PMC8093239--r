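#!/usr/bin/env Rscript
# Step 2 — discretize the fixture cohort and fit the network.
#
# Estimates root priors and child CPTs by conditional relative frequency
# on the 64-record fixture, and serializes the fitted model as YAML (the
# package's native document) and XMLBIF (for interoperability with
# standard Bayesian-network tools).

suppressPackageStartupMessages(library(distressbn))

dir.create("results", showWarnings = FALSE)

raw <- read_cohort_csv("results/cohort_fixture_raw.csv")
cohort <- discretize_cohort(raw, default_discretization_rules())
net <- fit_network(cohort, default_network_spec())
print(net)

write_network_yaml(net, "results/distress_network.yaml")
export_xmlbif(net, "results/distress_network.xml")
cat("fitted network -> results/distress_network.{yaml,xml}\n")

roots <- names(net$spec)[vapply(net$spec,
                                function(nd) length(nd$parents) == 0L,
                                logical(1))]
pri <- do.call(rbind, lapply(roots, function(v) {
  p <- prior_marginals(net)[[v]]
  data.frame(node = v, state = names(p), prior = as.numeric(p),
             prior_pct = round_half_away(100 * as.numeric(p)))
}))
write.csv(pri, "results/root_priors.csv", row.names = FALSE)
cat("root priors (integer percent):\n")
print(pri[, c("node", "state", "prior_pct")], row.names = FALSE)
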