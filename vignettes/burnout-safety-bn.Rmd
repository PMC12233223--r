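---
title: "Modelling burnout, resilience, and unsafe behavior with a discrete Bayesian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling burnout, resilience, and unsafe behavior with a discrete Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnoutbn)
```

## The problem and the model

Burnout is measured along three dimensions — emotional exhaustion (EE),
depersonalization (DP), and reduced personal accomplishment (PA) — and is a
plausible antecedent of unsafe workplace behavior, with psychological
resilience acting as a mediator. `burnoutbn` models six constructs measured
on one survey cohort of industrial (spinning and weaving) employees as
binary variables in a discrete Bayesian network:

* three parentless roots: EE, DP, PA (the "reduced" direction);
* poor resilience, child of the three burnout dimensions;
* poor safety compliance, child of the burnout dimensions and resilience;
* poor safety participation, the terminal node, child of all five others.

Every variable has states `low`/`high` with `low` desired. The joint
distribution factorizes node-by-node,
$P(x_1,\dots,x_6)=\prod_i P(x_i \mid \mathrm{pa}(x_i))$, so the model is
fully specified by the 12-arc DAG plus one conditional probability table
(CPT) per node. The packaged `study_network()` uses the cohort's published
high-state root marginals (EE 0.46, DP 0.53, PA 0.395) and the published
32-row participation CPT. The fitted resilience and compliance CPTs were
never published, so the package ships *synthetic* defaults built from an
additive formula — a base probability of the poor state plus a fixed
increment per adverse parent state (`default_resilience_cpt()`,
`default_compliance_cpt()`). The increments were chosen once so that each
burnout dimension and poor resilience raise the downstream poor-state
probabilities, matching the qualitative influence pattern of the original
analysis; they are labelled synthetic, are config-overridable, and no
package result that depends on them is presented as a reproduction of the
original numeric tables. For the same reason the original univariate /
multivariate sensitivity values, influence rankings, and the cohort AUC are
*not* reproduction targets: this package reproduces the published worked
examples that are self-contained (the participation CPT rows) and provides
the machinery for everything else.

## Instruments and scoring

Three instruments feed the model:

| Instrument | Items | Item range | Subscales |
|---|---|---|---|
| Maslach Burnout Inventory | 22 | 0–6 | EE (9), DP (5), PA (8) |
| Connor–Davidson Resilience Scale | 25 | 0–4 | 8/5/7/3/2 across five dimensions |
| Safety behavior assessment | 23 | 1–5 | compliance (12), participation (11) |

Subscale scores are plain item sums; the CD-RISC resilience total is the sum
of its five dimension scores. No individual items are reverse-scored —
direction is handled entirely at dichotomization. The MBI item-to-subscale
mapping is not dictated by the subscale sizes alone, so the package defaults
to the standard MBI-HSS assignment and accepts any alternative mapping
through `instrument_spec()`. Reliability is the standard Cronbach alpha,
$\alpha = \frac{k}{k-1}\left(1-\frac{\sum_i s_i^2}{s_T^2}\right)$, with an
explicit degenerate-input error when the total-score variance is zero.

### Median dichotomization

Each construct is cut at its sample median (even-$n$ medians are the mean of
the two middle order statistics, the convention of mainstream statistical
software). Direction conventions, with `low` always the desired state:

* **EE, DP**: raw score strictly above the median is `high`.
* **PA, resilience, compliance, participation**: the model variables are
  the *poor* variants, so a raw score strictly *below* the median is
  `high`; good raw scores map to `low`.
* **Ties** at the median always go to the desired `low` state — the rule
  must be deterministic and this keeps "at or better than the median"
  desirable under both directions.

The source analysis contains an internal inconsistency about the safety
variables: the instrument is explicitly scored so that higher raw scores
mean better behavior, yet the classification text ties the undesired state
to scores *above* the median. The package defaults to the self-consistent
reading (undesired = low raw safety score); the literal reading remains
selectable via `dichotomization_rules(..., safety_direction = "literal")`.
Because the six median thresholds of the real cohort were not reported,
real-data dichotomization cannot be replicated exactly; the synthetic
generator uses fixed mid-range thresholds instead (below).

## Exact inference

`infer_marginals()` computes posterior marginals under hard evidence by
sum-product variable elimination with a minimum-degree elimination order on
the moralized graph. At six binary nodes any order is fast; the heuristic is
there so the same code remains exact and efficient on somewhat larger
networks. Probabilities stay in linear space: the smallest non-zero joint
probability of a six-binary-node network is the product of at most six CPT
entries, far above double-precision underflow, so log-space bookkeeping
would add complexity without benefit. Evidence with probability zero raises
a structured `inconsistent_evidence_error` rather than returning an
arbitrary (e.g. uniform) distribution, because silently normalizing an
impossible scenario hides data/model mismatches. `enumerate_marginals()` is
a deliberately naive exhaustive-summation oracle kept solely as an
independent cross-check; the test suite asserts agreement within 1e-12 on
dozens of random DAGs up to 12 nodes.

## Parameter learning

`mle_cpts()` is crosstab estimation: each CPT row is the conditional
relative frequency of the child's states among records matching that parent
configuration. Parent configurations with no observations receive the
uniform fallback row (0.5/0.5 for binary nodes) — the same convention
visible in the published participation CPT, whose 0.5/0.5 rows correspond
to unobserved cells. An optional Laplace `pseudocount` (default 0) is
available when smoothing is preferable.

`em_learn()` handles missing cells under an ignorable (MCAR/MAR)
missingness assumption. The E-step is exact: the package enumerates the
joint state table once (grouping records by observed pattern so each
distinct pattern is completed only once) and distributes every incomplete
record over its completions in proportion to their joint probability under
the current parameters; the M-step renormalizes the expected counts.
Enumeration is the right tool at this scale — the study network has 64
joint states — and the implementation refuses networks beyond roughly 16
binary variables, where a junction-tree E-step would be needed instead.
Defaults: convergence when the observed-data log-likelihood improves by
less than 1e-6, at most 500 iterations, deterministic uniform
initialization (seeded random and user-supplied initializations are
options). Non-convergence at the iteration cap is flagged on the result,
not raised. The log-likelihood is recorded every iteration and is
non-decreasing — asserted per-iteration in the tests.

## Sensitivity analysis

A scenario clamps one (`univariate_sensitivity()`) or several
(`multivariate_sensitivity()`) variables to a state with probability 100%
and reports, for every other variable and state,
$\Delta P = 100\,[P(v{=}s \mid \text{evidence}) - P(v{=}s)]$ in percentage
points *relative to the no-evidence marginals* — the baseline that makes
scenario columns directly comparable. The pairwise conditional contrast
$\Delta p = P(\text{outcome}\mid\text{antecedent}) -
P(\text{outcome}\mid\overline{\text{antecedent}})$ is a separate operation
(`delta_p()`) since both framings are used in this literature. Report
tables round half-away-from-zero to integer percentage points (the
precision such tables are printed at); raw deltas are always retained, and
for binary nodes $\Delta P(\text{low}) = -\Delta P(\text{high})$ holds
exactly before rounding. `full_sensitivity_sweep()` runs all 12 univariate
scenarios plus the 2-, 3-, and 4-subsets of {EE, DP, PA, resilience}
clamped jointly all-low and all-high (22 scenarios); scenario-level
inference errors are collected into the result rather than aborting the
sweep.

`strength_of_influence()` summarizes one arc by the distance between the
child's conditional distributions with the parent flipped, across all
co-parent configurations: unweighted mean, maximum, and a mean weighted by
the model's joint probability of each co-parent configuration
(renormalized). The default distance is the maximum absolute
state-probability difference, with Euclidean and Hellinger selectable. The
GUI software used for the original influence rankings does not document its
metric, and no packaged metric reproduces those rankings from the published
CPT alone, so influence values should be compared within one metric and one
model only; the metric is recorded on the output.

## Cross-validation

`make_folds()` partitions records uniformly at random (sizes differing by
at most one, deterministic given the seed; stratification is deliberately
off because the original design specifies plain random subsets).
`cross_validate()` fits CPTs on the training folds (MLE, or EM when cells
are missing) and scores each held-out record by the posterior probability
of the target's `high` state given the record's other observed variables as
evidence. The original analysis never names its predicted node; the package
defaults to poor safety participation — the terminal node, the natural
outcome of the chain — and records the target in the output metadata.
Training-fold parent configurations left unobserved fall back to uniform
rows (logged); a held-out record whose evidence is impossible under the
trained model is scored with the trained prior of the target (logged).
`roc_curve()` sweeps thresholds over the unique scores with ties grouped,
integrates AUC by the trapezoidal rule (equal, by construction, to the
pairwise Mann–Whitney statistic with ties counted ½ — asserted against a
direct pairwise oracle in the tests), and reports the Youden-optimal
threshold alongside the default 0.5 operating point, since the original
operating threshold is unstated.

## The synthetic generator

`simulate_cohort()` stands in for the unavailable raw questionnaire data.
Its defaults are the study conditions: 200 respondents forward-sampled from
the packaged network, no missingness, no item noise. Respondent states are
drawn by ancestral sampling; item responses are then materialized per
construct by drawing a raw total uniformly from the integer range on the
correct side of that construct's threshold and partitioning it across the
construct's items by a random bounded composition. Generator thresholds are
fixed mid-range values (EE 27 of 0–54, DP 15 of 0–30, PA 24 of 0–48,
resilience 50 of 0–100, compliance 36 of 12–60, participation 33 of 11–55)
— the real medians being unpublished, mid-range cuts keep both state ranges
wide and the dichotomized cohort roughly balanced. With zero noise the
round trip items → scores → states is exact by construction; with noise
$\varepsilon$ each item is independently jittered one scale point with
probability $\varepsilon$. Missingness is injected MCAR only, because the
original analysis asserts nothing about its missingness mechanism and EM's
correctness argument covers MCAR/MAR.

What the generator does *not* emulate: item-level correlation structure
(an IRT or copula model), demographic composition, or the real instruments'
reliability coefficients. Tests that pass on synthetic cohorts therefore
validate the pipeline's logic and the estimators' statistical behavior, not
any psychometric claim about real respondents.

## Numerical conventions and test design

* CPT rows must sum to 1 within 1e-9; all returned distributions are
  normalized within the same bound, and inference agreement with the
  enumeration oracle is asserted at 1e-12.
* Problem sizes used by the test suite: 50 random networks of 2–12 binary
  nodes for the inference equivalence sweep; 5,000 forward-sampled records
  for parameter-recovery checks (2,000 for the EM variant); 50,000 samples
  for the Monte-Carlo check of the sampler against the packaged CPT; 10,000
  scores for the chance-level AUC check.
* Recovery checks compare learned CPT rows to generator truth per parent
  configuration. Because the crosstab estimator *equals* the empirical
  conditional frequency (asserted exactly against an independent
  contingency oracle), its per-entry error is pure binomial noise,
  $\mathrm{sd} = \sqrt{p(1-p)/n_c}$ for a configuration observed $n_c$
  times — about 0.07 at $n_c = 50$. Fixed per-entry tolerances near one
  standard error would therefore fail routinely for a provably correct
  estimator, so the package's recovery tests use noise-aware bounds: four
  standard errors, floored at 0.05 (complete data) or 0.07 (EM at 20%
  MCAR).
* All randomness flows through explicit integer seeds (`withr::with_seed`,
  so the caller's RNG state is never clobbered); the pipeline derives
  per-stage seeds deterministically from one global seed so a single
  integer reproduces a run byte-for-byte.

## Known limitations

* Structure learning is out of scope: the DAG is fixed theoretically.
* Only hard evidence is supported (no soft/virtual evidence), and all
  packaged variables are binary; the machinery accepts more states but the
  study semantics ("low desired") assume two.
* The EM E-step enumerates the joint space and is limited to ~16 binary
  variables.
* The packaged resilience and compliance CPTs are synthetic; analyses of
  the packaged network characterize the machinery, not the original cohort.
* Real-data medians, the original influence metric, the ROC target node,
  and its operating threshold are unknown, so those published values are
  informative context, not validation targets.
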