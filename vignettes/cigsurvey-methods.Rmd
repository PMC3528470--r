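---
title: "Methods: conditional-independence graphs for mixed survey data"
author: "cigsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional-independence graphs for mixed survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Population surveys of functioning and disability measure many outcomes at
once: impairments in body functions, limitations in activities and
participation (A&P), perceived health, and a battery of personal,
socio-economic and environmental context variables. The "disability
paradox" is the repeated observation that people with severe impairments
often report good perceived health. One resolution is structural: if
impairment translates into A&P limitation only *through* contextual factors
(supports, marital status, income, education, gender, age, employment), and
perceived health responds to A&P limitation rather than to impairment
itself, then the paradox dissolves once context is taken into account.

Claims of this form are statements about *conditional independence*: two
variables are conditionally independent when, given all the remaining
variables, knowing one tells you nothing further about the other. The
natural representation is an undirected conditional-independence graph
(CIG) over the `p = 20` modeling variables: a missing edge between two
nodes means conditional independence given the other `p - 2`.

`cigsurvey` implements the full workflow: index construction from survey
item batteries, CIG estimation with graphical random forests under
stability selection, structural interrogation of the estimated graph, and a
synthetic-cohort generator with a known ground truth for validating the
estimator's error control and recovery behaviour.

## Sum indices and the modeling table

Survey items arrive on heterogeneous scales, so each item is first
dichotomized to a 0/1 problem indicator (`1` = a problem is present; for
body mass index the rule is "over 30 or under 16", bounds exclusive). Five
sum indices count these indicators: impairment (9 items, range 0–9), pain
sites (6, 0–6), A&P limitation (13, 0–13), perceived social support (4,
0–4) and social network utilization (5, 0–5). For the support and network
batteries the indicator codes the presence of a resource rather than a
problem, matching the published high means (3.3 and 3.2).

Only the body-mass-index threshold is published; every other item rule
defaults to a pass-through of a 0/1 response, and all rules are plain data
(`index_specs_from_config()`), so a user of the real Swiss Health Survey
can substitute item-specific cut-offs without touching code.

The modeling table holds exactly twenty variables: perceived health
(ordinal 1 = very good … 5 = very poor; the published median of 2 fixes the
orientation), the pain/impairment/A&P counts, age, alcohol consumption,
education years, income, the support and network counts, seven binary
indicators (male, married, smoker, low physical activity, paid employment,
migration background, work restriction), and three canton-level macro
indicators (GDP per capita, Gini coefficient, crime rate) constant within
canton. Work restriction is treated as a standalone binary variable
("health problem restricts work") rather than as an item of the A&P
battery; this is what brings the roster to twenty. Marital status is
collapsed to married/not. A missing component item makes its sum index
missing, and any missing modeling variable removes the respondent
(casewise deletion) — with under 0.85% of replies missing the choice of
missing-data handling is immaterial, and no imputation or survey weighting
is performed.

## The synthetic cohort and its ground truth

The real survey microdata are access-restricted, so the package ships a
generator whose *ground truth* is a CIG shaped like the published result:

* impairment–A&P limitation and impairment–perceived health non-adjacent;
* A&P limitation–perceived health adjacent;
* two impairment-to-limitation pathways through the contextual block
  (support–married–income–education–gender–employment, and
  support–married–age–employment);
* five isolated nodes (social network, migration background, smoker, work
  restriction, low physical activity);
* a separate three-node macro component (GDP–Gini–crime).

Adjacencies the published narrative does not pin down are generator
configuration: alcohol attaches to gender, and three demographic chords
(male–age, education–age, income–age) are added. The chords matter: data
are simulated along an *oriented* version of the truth, and the simulated
conditional-independence structure equals the undirected truth exactly only
when the orientation creates no immoralities (no node with two non-adjacent
earlier neighbours). Such an orientation exists only for chordal graphs,
and the two published pathways by themselves form a chordless six-cycle;
the three chords — each sociologically natural — make the graph chordal,
and `ground_truth_graph()` verifies the property (via maximum-cardinality
search) for any user-supplied truth. We considered the alternative of a
latent Gaussian copula with the truth as precision support, but rejected
it: thresholding a latent variable leaks dependence around the observed
variable (an observed binary parent does not block the path through its
latent version), which measurably distorts the conditional-independence
structure of discretized columns.

Each variable is then a *binned/thresholded Gaussian* structural equation:
its latent score is the sum of its standardized already-generated parents
times a structural coefficient, plus unit Gaussian noise; cut points on the
latent score produce the observed value. One coherent link family covers
binary (single threshold), ordinal and count variables (cut points at the
target cumulative probabilities) and continuous ones (moment or quantile
maps, including the skewed lognormal income and zero-inflated lognormal
alcohol distributions).

Calibration (`calibrate_marginals()`) runs a one-off simulation of 50,000
respondents along the generation order and freezes the empirical quantiles
of each latent score as that variable's intercepts. This matches the
published cohort description by construction: count distributions are
beta-binomial mixtures matched to the published prevalence, mean and SD
(e.g. impairment: 70.6% with at least one problem, mean 1.4, SD 1.3);
perceived health gets category probabilities (0.25, 0.55, 0.15, 0.04, 0.01)
consistent with the published median and decile quantiles. Item batteries
are back-filled by distributing each index count over its items with
weights taken from the published specific-problem prevalences (42% lack of
energy … 1.5% speaking problems; 44% back pain … 9% chest pain; 12% major
household tasks … 0.5% eating), so that re-summing the items reproduces the
index exactly; the body-mass-index item is emitted on its measurement scale,
outside the 16–30 band exactly when the item is positive.

Default structural coefficient: 0.8 per standardized parent (standardized
node-model signal ≈ 0.5–0.75, deliberately strong so that structure
recovery is testable at reduced sample sizes). Edges incident to the A&P
count get 10/7 of the default: with only 15.8% of respondents above zero,
discretization attenuates the observable signal and the compensation keeps
the effective signal comparable across edges. Macro edges get 9/7 because
they are estimated from only 26 canton-level draws. Canton sizes are
proportional to a Dirichlet draw (gamma shape 10); macro indicators are
drawn once per canton — mutually dependent at the canton level, independent
of every individual-level variable — with the Gini range (≈0.25–0.5)
matching the published spread across cantons.

Missingness is injected completely at random at 0.75% of cells (the survey
reports under 0.85% of replies missing). One master seed drives canton
sizes, macro draws, respondent noise, item back-fill and missingness
through a documented splitting scheme; a fixed seed gives bit-identical
cohorts.

One subtlety discovered during validation: because the three macro columns
share the canton partition, they are deterministically linked within any
*realized* cohort even when the truth has no macro edges — an estimator
working at the respondent level correctly finds the macro triangle. Null
simulations that require twenty mutually independent variables must
therefore draw the macro columns independently per respondent
(`generator_config(macro_clustered = FALSE)`).

What the generator does *not* emulate: real item wordings and response
scales, survey stratification and weighting, informative missingness
(an MCAR mechanism only), response shift, and real cantonal statistics.
Passing recovery tests therefore show that the estimator finds structures
of this shape at these signal strengths — not that the published graph is
correct.

## Graphical random forests with stability selection

Estimation follows the neighbourhood-screening idea: regress each of the
`p` variables on the remaining `p - 1` with a random forest —
classification forests for binary targets, regression forests for ordinal,
count and continuous targets (treating 5–14-level ordinals as classes would
fragment them) — and score candidate edges by variable importance.

* **Importance.** Permutation importance (not impurity), which is less
  biased across mixed predictor scales; negative values are truncated to
  zero.
* **Symmetrization.** Each node's importance vector is normalized to sum
  to one, scaled by the model's out-of-bag skill (one minus the ratio of
  out-of-bag error to the intercept-only error, clamped to `[0, 1]`), and
  the score of edge \{a, b\} is the mean of the two directed
  contributions. The skill factor is essential: a target with no real
  predictors has a near-zero importance total, and plain normalization
  would inflate its noise into scores large enough to displace weak true
  edges from the top of the ranking.
* **Stability selection.** 50 complementary subsample pairs (100 disjoint
  half-samples of size `floor(n/2)`) rather than with-replacement
  bootstrap: the error-control theory we rely on is stated for
  complementary-pairs subsampling. On every half-sample the top
  `q(V) = floor(sqrt(V (2 pi_thr - 1) E_total))` edges are recorded
  (`E_total = p(p-1)/2`); an edge enters the graph at bound `V` when its
  selection frequency reaches `pi_thr = 0.75`. `V` bounds the expected
  number of falsely selected edges via
  `E[FP] <= q^2 / ((2 pi_thr - 1) E_total)`; the default report uses
  `V <= 5`, labelling each edge with the smallest bound at which it enters
  (smaller label = more stable). Because `q(V)` is non-decreasing and
  `pi_thr` fixed, edge sets are nested across bounds. The bound cannot
  meaningfully be set to 0 — that graph is empty by construction.
* **Forests.** 100 trees per node model, `mtry = ceiling(sqrt(p - 1))`,
  depth capped at 6 with leaves of at least 5% of the fitting sample.
  The caps are a deliberate screening choice: the forests rank predictors,
  they are not tuned predictors themselves, and shallow large-leaf trees
  keep the 100 half-samples × `p` models per estimate tractable on one
  CPU. Both caps are exposed in `forest_control()`.
* **Determinism.** All randomness flows from one master seed (subsample
  permutations; per-forest seeds derived as
  `(seed * 48271 + b*1000 + half*100 + j) mod (2^31 - 19)`), so reruns are
  bit-reproducible, and ties in the top-`q` ranking break by lexicographic
  node-pair order.

Known limitations: importance-based screening does not separate direct
from indirect association as sharply as a parametric partial-correlation
estimate would; strongly connected neighbourhoods can promote a
distance-two pair into the selected set. In our recovery simulations such
extra edges appear within the densely connected contextual block, are few
(2–3 at `V = 5`, inside the expected-false-positive budget), and do not
affect the structural claims (isolation, the impairment–A&P
non-adjacency, separation through the contextual block). The method makes
no causal statements and does not report effect signs.

## Problem sizes used by the tests and the acceptance script

Simulation checks are run at sizes chosen to keep the default suite fast
while leaving the contracts intact; these are the package's study
conditions and are stated here once:

* generator calibration: full scale, one cohort of n = 18,760 (test) —
  the three headline prevalences must land within ±1.5 percentage points;
* error control: null cohorts of n = 1,000 at default settings (the
  default 0.75% missingness leaves ≈ 690 complete rows), 5 replicates in
  the test suite and 20 in `scripts/acceptance.R`; mean selected edges at
  `V = 5` must not exceed 5;
* structure recovery and macro-removal sensitivity: ten complete cohorts
  of n = 1,000 with 30 subsample pairs, matched seeds across the
  with/without-macro arms;
* the exhaustive checks (index ranges over all `2^k` response patterns,
  path enumeration against a brute-force DFS, top-`q` selection against a
  full sort) are exact and run at full scope.

## Numerical choices and degenerate inputs

Beta-binomial count fits clamp the overdispersion parameter to
`[1e-6, 0.98]` and fall back gracefully when a target is on the boundary;
infeasible targets (prevalence outside `(0, 1]`, mean incompatible with
prevalence) are errors. Constant target columns are refused as degenerate
outcomes. Tables with missing values are refused by the estimator —
casewise deletion is the documented contract. Empty inputs keep their
schema (a zero-row modeling table still has the twenty columns). Graph
I/O uses GraphML (round-trips the generation order as a scalar attribute)
and DOT/CSV for export.
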