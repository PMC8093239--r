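#' Default distress-network structure (documented reconstruction)
#'
#' The 12-node structure used throughout the package: lifestyle and
#' psychosocial inputs feeding a four-state psychological-distress outcome
#' node. The published network diagrams are not machine readable, so this
#' arc set is a reconstruction chosen to reproduce the qualitative
#' propagation pattern of the reported scenarios (certainty for less
#' healthy eating reaches physical-health quality of life and distress;
#' certainty for low social connectedness reaches cyberstrife,
#' social-relationships quality of life and distress; evidence on the
#' outcome node reaches every input). Treat it as a default, not ground
#' truth: any structure can be supplied via [bn_spec()] or a network file.
#'
#' Arcs: eating_behaviours -> qol_physical, psychological_distress;
#' social_connectedness -> cyberstrife, qol_social, psychological_distress;
#' physical_activity -> qol_physical; sleep -> qol_physical;
#' mindfulness -> metacognition, impulsivity;
#' qol_psych, metacognition, impulsivity -> psychological_distress.
#'
#' @return A `bn_spec` with 12 nodes; the outcome node
#'   `psychological_distress` has states well/mild/moderate/severe, all
#'   other nodes are dichotomous.
#' @export
default_network_spec <- function() {
  bn_spec(list(
    bn_node("sleep", c("good", "poor")),
    bn_node("physical_activity", c("less", "more")),
    bn_node("eating_behaviours", c("less_healthy", "more_healthy")),
    bn_node("social_connectedness", c("low", "high")),
    bn_node("mindfulness", c("less", "more")),
    bn_node("qol_psych", c("low", "high")),
    bn_node("cyberstrife", c("no", "yes"), parents = "social_connectedness"),
    bn_node("qol_social", c("low", "high"), parents = "social_connectedness"),
    bn_node("qol_physical", c("low", "high"),
            parents = c("eating_behaviours", "physical_activity", "sleep")),
    bn_node("metacognition", c("low", "high"), parents = "mindfulness"),
    bn_node("impulsivity", c("low", "high"), parents = "mindfulness"),
    bn_node("psychological_distress",
            c("well", "mild", "moderate", "severe"),
            parents = c("eating_behaviours", "social_connectedness",
                        "qol_psych", "metacognition", "impulsivity"))))
}
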