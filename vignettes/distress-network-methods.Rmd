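---
title: "Modelling adolescent psychological-distress risk with a discrete Bayesian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adolescent psychological-distress risk with a discrete Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distressbn)
```

## The model

`distressbn` represents the joint distribution of twelve categorical
psychosocial and lifestyle variables as a discrete Bayesian network: a
directed acyclic graph in which each node carries a conditional
probability table (CPT) given its parents, and the joint factorizes as

$$P(x_1, \dots, x_n) \;=\; \prod_{i=1}^{n} P\!\left(x_i \mid
\mathrm{pa}(x_i)\right).$$

The outcome node is psychological distress, measured by the Kessler K10
and carrying the four established screening states (well / mild /
moderate / severe); every other variable is dichotomous. Inference is
exact: evidence is hard (a node fixed to one state, the "certainty" of a
scenario), and posteriors are computed by variable elimination with a
min-degree elimination order on the moralized graph. Correctness does not
depend on the order — at twelve nodes any order is affordable — so the
heuristic is purely a cost device. A brute-force enumeration oracle
(`enumerate_posterior_oracle()`) computes the same posteriors from the
full joint table and is used throughout the tests; it refuses state
spaces above $10^7$ configurations.

Conditioning on the outcome node and reading posteriors of its ancestors
is the diagnostic, Bayes-rule direction ("backwards reasoning"); the same
engine serves both directions.

### Network structure is an input

The published diagrams of the original network are not machine readable,
so `default_network_spec()` ships a documented *reconstruction*: six
roots (sleep, physical activity, eating behaviours, social connectedness,
mindfulness, psychological-domain quality of life) and arcs

* eating behaviours → QOL physical, psychological distress
* social connectedness → cyberstrife, QOL social, psychological distress
* physical activity → QOL physical; sleep → QOL physical
* mindfulness → metacognition, impulsivity
* QOL psychological, metacognition, impulsivity → psychological distress

chosen to reproduce the qualitative propagation pattern of the reported
scenarios. One structural consequence worth knowing: sleep and physical
activity reach the rest of the network only through the collider at QOL
physical, so evidence on the outcome node alone cannot move them — they
are d-separated. Any other structure can be supplied via `bn_spec()`, a
network YAML file or XMLBIF.

## Discretization

Two instruments have validated cutoffs: the K10 (well < 20, mild 20–24,
moderate 25–29, severe ≥ 30; the printed band edges leave a score of
exactly 20 unassigned, and the package places it in the mild band, the
standard K10 convention — configurable via the rule's `cutpoints`) and
the PSQI (good sleep ≤ 5 on the 0–21 global score). Every other
instrument is dichotomized at the *midpoint of its theoretical score
range* (the 50th percentile of the possible range, not the empirical
median), with the boundary value assigned to the upper band. The
cyberstrife flag is a precomputed boolean passed through, because
item-level scoring of the source questionnaire is not specified.

Theoretical ranges for the midpoint instruments are not published with
the model, so the package defaults are reconstructions from the
instruments' item counts and response scales (SCS 15–90, HBSC physical
activity 3–21, FFQ eating 6–42, MCQ-A 30–120, MAAS-A 14–84, BIS-Brief
8–32, WHOQOL-BREF domains on the 0–100 transformed scale). They are
configuration data: override them per deployment through
`default_discretization_rules(ranges = ...)` or a run-config file.
Each rule is checked at load time to partition its range with no gaps or
overlaps. Records with any missing score are excluded (complete-case)
with a logged count; no imputation is attempted.

## Parameter estimation

Root nodes take relative-frequency priors; each child CPT row is the
conditional relative frequency of the child's states among cohort records
matching that parent configuration. With 64 records and an outcome node
with five dichotomous parents (32 configurations), many configurations
are unobserved; those rows are set to the uniform distribution rather
than smoothing the observed rows, preserving plain-frequency
parameterization while keeping every CPT well defined. An optional add-α
pseudo-count (`alpha`, default 0) is available for users who prefer
global smoothing. A consequence of the uniform fallback is visible in the
baseline: the fitted fixture network puts about 75% on "well", below the
84% raw marginal, because unobserved adverse parent configurations
carry a little prior mass and contribute uniform outcome rows. The
original study's published 83% baseline depends on its unpublished joint
data (and possibly tool-internal smoothing), so child-node baselines here
are qualitative references, not reproduction targets.

## Scenarios and the percent-change statistic

A scenario fixes one or more nodes to a state and propagates. The
reported statistic per node state is the percent change

$$\Delta_{\%} = \frac{P_{\text{evidence}} - P_{\text{baseline}}}
{P_{\text{baseline}}} \times 100,$$

computed on unrounded probabilities by `run_scenario()`. The *report
layer* (`render_scenario_table()`) rounds probabilities to integer
percentages half-away-from-zero and recomputes $\Delta_{\%}$ from the
rounded values: the published scenario tables are internally consistent
at printed precision (e.g. 34% → 43% prints as +26, 83% → 61% as −27),
and this convention lets a reader reproduce every printed change cell
from the printed percentage columns. The unrounded statistic is always
retained alongside (`delta_pct_exact`). A zero baseline leaves the
statistic undefined — reported as `NA`, raised as an error in
`percent_change()` — never ±∞.

```{r scenario}
net <- fit_network(generate_fixture_cohort(), default_network_spec())
res <- run_scenario(net, preset_scenarios()$unhealthy_eating)
render_scenario_table(res)[c(17:18, 23:26), ]
```

## Sensitivity analysis

`sensitivity_values()` performs one-way sensitivity analysis: for each
CPT entry $\theta$, the derivative of a target posterior with respect to
$\theta$, with the complements of $\theta$'s row co-varied proportionally
so the row stays normalized (the standard scheme for one-way BN
sensitivity). Under proportional covariation both the unnormalized target
probability and the evidence probability are linear in $\theta$, so the
posterior is a quotient of linear functions; the implementation recovers
the linear coefficients exactly from two inference evaluations per
parameter and differentiates the quotient analytically. There is no
finite-difference truncation error; the test suite nonetheless
cross-checks against an independent central-difference oracle at
$h = 10^{-4}$.

Two numerical details. Parameters of nodes d-separated from the target
given the evidence have derivative *exactly* zero, because inference
prunes irrelevant CPTs (ancestral set restricted to the moral-graph
component of the query) before elimination — the perturbed table never
enters the computation. And a parameter currently at 1 has complements at
0, where proportional covariation is undefined; such parameters are
flagged `degenerate` and handled one-sided, redistributing mass uniformly
over the complements.

Node-level influence is aggregated as the maximum absolute derivative
over the node's parameters (the conventional headline sensitivity value;
`sum` and `l2` are available), with exact ties broken lexicographically
and flagged. The original study's specific ranking of modifiable inputs
depends on its unpublished joint data; on the shipped fixture the ranking
is computed and reported by `analysis/05_sensitivity.R` but not asserted.

## The synthetic cohort generator

No participant-level data are distributed with the original analysis, so
the package generates its own cohorts at two levels of fidelity.

**The frozen fixture** (`generate_fixture_cohort()`) reproduces the
published per-variable summary *exactly*: 64 records whose discretized
counts match the reference table for all twelve variables (e.g. distress
54/7/2/1, physical activity 7/57, cyberstrife 42/22). Marginals do not
determine a joint, so the fixture fixes one: records are ranked by a
latent distress draw under a fixed documented seed, and each variable's
adverse-state quota is filled from the most-distressed end. This quota
assignment produces nested co-occurrence of adverse states — plausible,
deterministic, byte-reproducible, and deliberately frozen. Its raw-score
form (`fixture_raw_cohort()`, also shipped as
`inst/extdata/fixture_cohort_synthetic.csv` — a synthetic file, as the
name says) places each score deterministically inside the band implied by
the record's state, so discretization recovers the fixture exactly.

**Stochastic cohorts** (`generate_raw_cohort()`) draw a latent standard
normal distress factor per participant; each instrument score is a
monotone transform of $\lambda z + \sqrt{1-\lambda^2}\,\varepsilon$ (a
Gaussian copula), with band thresholds placed so expected state marginals
equal the configured targets exactly, then rounded within the band for
integer instruments. Defaults: target marginals are the fixture
proportions; loadings are a single fixed set chosen to give strong
association for the K10 (0.8), moderate association for proximal
psychological measures (0.4–0.6) and weaker association for behavioural
measures (0.35) — plausible magnitudes for self-report psychosocial
instruments, set once and not tuned. Setting all loadings to 0 yields
pairwise-independent variables, which the tests verify by χ².

What the generator does *not* emulate: item-level response processes,
multi-factor dependence (one latent factor induces a single-rank
correlation structure), longitudinal waves, demographic covariates, and
the original cohort's true joint. Tests passing on these cohorts
demonstrate correctness of the machinery — estimation, inference,
propagation, sensitivity — not epidemiological conclusions about real
adolescents.

`sample_from_network()` completes the loop: ancestral sampling from any
fitted network, used for the parameter-recovery property (50 000 samples
from a fixed 5-node network refit to within total-variation 0.02 per CPT
row).

## Numerical conventions and degenerate inputs

* Probabilities are carried at full double precision; rounding happens
  only in the report layer.
* All returned distributions are normalized; the engine's tolerance for
  CPT row sums is $10^{-9}$ on input, and serialization writes 17
  significant digits so YAML and XMLBIF round-trips are lossless at
  $10^{-12}$.
* Evidence with probability zero under the model raises an error rather
  than returning NaN.
* Cycles and dangling parent references are structural errors naming the
  offending nodes (one directed cycle is printed).
* Unobserved parent configurations: uniform CPT rows (see above); an
  empty cohort is an estimation error.

## Problem sizes

The analysis scripts and the test suite run at desk scale by design: the
12-node network (joint space $2^{11} \times 4 = 8192$), property tests
over 100 randomized networks of up to 12 nodes and 4 states with the
joint capped at 20 000 configurations, 50 randomized 6-node networks for
the sensitivity cross-check, 10 000-record cohorts for calibration
checks, and 50 000 ancestral samples for parameter recovery. The full
suite completes in well under a minute on one core.

## Known limitations

* The default structure and the instrument ranges are reconstructions;
  conclusions that depend on the exact arc set or the exact joint of the
  original cohort (child-node baselines, the published multi-node
  scenario tables, the published sensitivity ranking) are reproducible
  only qualitatively.
* Hard evidence only: the scenario semantics is conditioning, not
  intervention (no do-calculus), and no soft/virtual evidence is
  supported.
* No structure learning, no continuous or temporal nodes, no approximate
  inference — out of scope by design.
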