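# burnoutbn

Discrete Bayesian-network analysis of how job burnout and psychological
resilience relate to unsafe workplace behavior.

Occupational-safety studies commonly measure burnout with the Maslach
Burnout Inventory (emotional exhaustion EE, depersonalization DP, and
reduced personal accomplishment PA), resilience with the Connor–Davidson
Resilience Scale, and safety behavior with a two-dimension questionnaire
(safety compliance and safety participation). `burnoutbn` implements the
full analysis chain used to link these six constructs in a cross-sectional
survey cohort:

1. **Survey scoring** — subscale sums, Cronbach's alpha, median
   dichotomization of each construct into a binary `low`/`high` model
   variable, with `low` the desired state throughout (high EE/DP mean raw
   scores above the median; "poor" resilience/compliance/participation and
   reduced PA mean raw scores below it).
2. **The network** — six binary nodes with the three burnout dimensions as
   parentless roots, arcs from each burnout dimension to resilience,
   compliance, and participation, from resilience to both safety nodes, and
   from compliance to participation. The joint distribution factorizes as
   `P(x1..x6) = prod_i P(xi | parents(xi))`, one conditional probability
   table (CPT) per node. The packaged network carries the cohort's published
   root marginals and participation CPT; the unpublished resilience and
   compliance CPTs default to clearly-labelled synthetic tables.
3. **Exact inference** — posterior marginals under hard (100%) evidence by
   sum-product variable elimination, checked against an exhaustive
   enumeration oracle.
4. **Parameter learning** — CPTs by crosstab maximum likelihood on complete
   records, or by expectation–maximization when cells are missing
   (observed-data log-likelihood is non-decreasing per iteration).
5. **Sensitivity analysis** — percentage-point shifts of every node's
   posterior when one or several variables are clamped to a state with
   certainty; Delta-p; distance-based arc strength of influence.
6. **Validation** — k-fold cross-validation of held-out predictions with
   ROC/AUC and confusion-matrix metrics.
7. **Synthetic cohorts** — a generator that forward-samples states from the
   network and materializes item-level questionnaire responses, so the whole
   pipeline is testable without confidential respondent data.

Networks interchange as JSON, YAML, or GeNIe XDSL files. A thin CLI wrapper
lives at `inst/cli/burnoutbn.R`.

## Worked example

```r
library(burnoutbn)

net <- study_network()
infer_marginals(net)
#> prior marginals
#>                  low   high
#> EE            0.5400 0.4600
#> DP            0.4700 0.5300
#> PA            0.6050 0.3950
#> resilience    0.6300 0.3700
#> compliance    0.5726 0.4274
#> participation 0.4947 0.5053
```

The prior probability of poor safety participation is 0.505; the three root
rows are the cohort's observed high-state frequencies. Clamping emotional
exhaustion to its high state with certainty:

```r
univariate_sensitivity(net, "EE", "high")
#> <sensitivity_report> EE high 100%
#>               delta_low delta_high
#> DP                 0.00       0.00
#> PA                 0.00       0.00
#> resilience       -16.20      16.20
#> compliance       -12.74      12.74
#> participation    -15.13      15.13
```

The other burnout roots are untouched (they are d-separated from EE without
evidence on a common descendant) while poor resilience, compliance, and
participation each become more likely — the deltas are percentage points
relative to the no-evidence marginals. An end-to-end synthetic run:

```r
cohort <- simulate_cohort(generator_config(n = 200, seed = 1))
scores <- score_survey(cohort$items)
states <- dichotomize(scores, dichotomization_rules(compute_medians(scores[-1])))
struct <- bn_network(study_variables(), study_arcs())
preds  <- cross_validate(states[-1], struct, target = "participation", k = 10, seed = 1)
roc_curve(preds)
#> <roc_result> AUC 0.698 (100 positives, 100 negatives); Youden threshold 0.444
round(classification_metrics(preds), 3)
#> sensitivity specificity    accuracy
#>       0.760       0.610       0.685
```

so a network learned from 200 simulated respondents predicts held-out poor
safety participation well above chance from the other five variables.

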