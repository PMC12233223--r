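# Packaged six-variable study network: three burnout dimensions (EE, DP,
# reduced PA) as parentless roots, poor resilience, poor safety compliance,
# and poor safety participation. "Low" is the desired state of every
# variable.

#' Variables of the packaged study network
#' @return Character vector of the six model variable names.
#' @export
study_variables <- function() {
  c("EE", "DP", "PA", "resilience", "compliance", "participation")
}

#' Arc set of the packaged study network
#'
#' Twelve arcs: each burnout dimension points at resilience, compliance, and
#' participation; resilience points at compliance and participation;
#' compliance points at participation.
#'
#' @return data.frame with columns `parent`, `child`.
#' @export
study_arcs <- function() {
  burnout <- c("EE", "DP", "PA")
  rbind(
    expand.grid(parent = burnout, child = c("resilience", "compliance", "participation"),
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
    data.frame(parent = c("resilience", "resilience", "compliance"),
               child = c("compliance", "participation", "participation")))
}

#' Published conditional probability table for poor safety participation
#'
#' The packaged CPT of the terminal node, conditioned on its five parents
#' (EE, DP, reduced PA, poor resilience, poor safety compliance), transcribed
#' from the study's published table. Rows such as (EE=low, DP=low, PA=low,
#' resilience=high, compliance=high) -> P(high) = 0.923 are exact published
#' values; the 0.50/0.50 rows correspond to parent configurations without
#' observed respondents.
#'
#' @return A [bn_cpt()] for `participation`.
#' @export
participation_cpt <- function() {
  parents <- c("EE", "DP", "PA", "resilience", "compliance")
  rows <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
EE   DP   PA   resilience compliance p_low p_high
low  low  low  low        low        1.000 0.000
low  low  low  low        high       1.000 0.000
low  low  low  high       low        0.481 0.519
low  low  low  high       high       0.077 0.923
low  low  high low        low        0.800 0.200
low  low  high low        high       0.286 0.714
low  low  high high       low        0.000 1.000
low  low  high high       high       0.000 1.000
low  high low  low        low        0.750 0.250
low  high low  low        high       0.000 1.000
low  high low  high       low        0.500 0.500
low  high low  high       high       0.500 0.500
low  high high low        low        0.625 0.375
low  high high low        high       0.333 0.667
low  high high high       low        0.500 0.500
low  high high high       high       0.500 0.500
high low  low  low        low        0.500 0.500
high low  low  low        high       0.444 0.556
high low  low  high       low        0.500 0.500
high low  low  high       high       0.500 0.500
high low  high low        low        0.600 0.400
high low  high low        high       0.167 0.833
high low  high high       low        0.500 0.500
high low  high high       high       0.500 0.500
high high low  low        low        0.500 0.500
high high low  low        high       0.500 0.500
high high low  high       low        0.000 1.000
high high low  high       high       0.000 1.000
high high high low        low        0.571 0.429
high high high low        high       0.429 0.571
high high high high       low        0.000 1.000
high high high high       high       0.048 0.952
")
  cpt_from_rows("participation", parents, rows)
}

#' Published root marginals
#'
#' High-state relative frequencies of the three parentless burnout variables
#' in the study cohort (n = 200): EE 0.46, DP 0.53, reduced PA 0.395.
#'
#' @return Named numeric vector of high-state probabilities.
#' @export
study_root_marginals <- function() {
  c(EE = 0.46, DP = 0.53, PA = 0.395)
}

# synthetic additive CPT: P(child = high | parents) = base + sum of the
# per-parent increments for parents in their high state
additive_cpt <- function(child, parents, base, increments) {
  grid <- expand.grid(stats::setNames(rep(list(c("low", "high")), length(parents)),
                                      parents),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  p_high <- base + as.matrix(grid == "high") %*% increments[parents]
  p_high <- round(pmin(pmax(as.numeric(p_high), 0), 1), 3)
  rows <- cbind(grid, p_low = 1 - p_high, p_high = p_high)
  cpt_from_rows(child, parents, rows)
}

#' Synthetic default CPT for poor resilience
#'
#' The study does not publish the fitted resilience CPT, so the packaged
#' default is a synthetic table: the probability of poor resilience rises
#' additively with each burnout dimension in its high state
#' (base 0.10; EE +0.30, DP +0.10, PA +0.20), qualitatively matching the
#' published positive-influence pattern. Override it for real analyses.
#'
#' @return A [bn_cpt()] for `resilience`.
#' @export
default_resilience_cpt <- function() {
  additive_cpt("resilience", c("EE", "DP", "PA"),
               base = 0.10, increments = c(EE = 0.30, DP = 0.10, PA = 0.20))
}

#' Synthetic default CPT for poor safety compliance
#'
#' The study does not publish the fitted compliance CPT; the packaged
#' default is a synthetic additive table (base 0.15; EE +0.17, DP +0.17,
#' PA +0.07, resilience +0.22) with the published positive-influence signs.
#' Override it for real analyses.
#'
#' @return A [bn_cpt()] for `compliance`.
#' @export
default_compliance_cpt <- function() {
  additive_cpt("compliance", c("EE", "DP", "PA", "resilience"),
               base = 0.15,
               increments = c(EE = 0.17, DP = 0.17, PA = 0.07, resilience = 0.22))
}

#' The packaged study network
#'
#' Six binary variables over the published 12-arc structure. Root CPTs use
#' the published cohort marginals, the participation CPT is the published
#' table, and the resilience and compliance CPTs — unpublished in the study —
#' default to clearly-labelled synthetic tables
#' ([default_resilience_cpt()], [default_compliance_cpt()]).
#'
#' @param resilience_cpt,compliance_cpt Replacement CPTs, e.g. learned from
#'   data with [mle_cpts()] or [em_learn()].
#' @param root_marginals Named high-state probabilities for EE, DP, PA.
#' @return A validated [bn_network()].
#' @export
study_network <- function(resilience_cpt = default_resilience_cpt(),
                          compliance_cpt = default_compliance_cpt(),
                          root_marginals = study_root_marginals()) {
  roots <- lapply(names(root_marginals), function(v)
    bn_cpt(v, character(0), c(1 - root_marginals[[v]], root_marginals[[v]])))
  cpts <- c(roots, list(resilience_cpt, compliance_cpt, participation_cpt()))
  bn_network(study_variables(), study_arcs(), cpts)
}
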