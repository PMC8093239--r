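#!/usr/bin/env Rscript
# Step 5 — one-way sensitivity analysis of the baseline outcome posterior.
#
# For the target P(psychological distress = well) with no evidence,
# computes the derivative of the posterior with respect to every CPT
# parameter under proportional covariation, and ranks nodes by their
# maximum absolute derivative. The resulting ranking of modifiable input
# nodes is reported; it depends on the fixture's reconstructed joint, so
# it is descriptive, not a reproduction of the original study ranking.

suppressPackageStartupMessages(library(distressbn))

net <- read_network_yaml("results/distress_network.yaml")

q <- sensitivity_query("psychological_distress", "well")
sv <- sensitivity_values(net, q)
sv <- sv[order(-abs(sv$derivative)), ]
write.csv(sv, "results/sensitivity_values.csv", row.names = FALSE)
cat("per-parameter derivatives -> results/sensitivity_values.csv\n")

rk <- rank_nodes_by_sensitivity(sv)
write.csv(rk, "results/sensitivity_ranking.csv", row.names = FALSE)
cat("\nnode ranking by max |d P(well) / d theta|:\n")
print(rk, row.names = FALSE)

modifiable <- c("eating_behaviours", "social_connectedness",
                "physical_activity", "sleep", "mindfulness")
cat("\nmost influential modifiable input node:",
    rk$node[rk$node %in% modifiable][1], "\n")
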