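# Hard-evidence sensitivity analysis: how posting 100% evidence on one or
# several variables shifts every other variable's posterior, in percentage
# points relative to the no-evidence marginals; plus Delta-p and
# distance-based arc strength of influence.

make_sensitivity_report <- function(net, evidence, label = NULL) {
  evidence <- check_evidence(net, evidence)
  if (length(evidence) == 0)
    stop_validation("sensitivity scenarios need at least one evidence variable")
  baseline <- infer_marginals(net)
  posterior <- infer_marginals(net, evidence)
  delta <- lapply(names(net$variables), function(v)
    100 * (posterior[[v]] - baseline[[v]]))
  names(delta) <- names(net$variables)
  structure(list(
    label = label %||% paste(names(evidence), evidence, sep = "=", collapse = ", "),
    evidence = evidence,
    baseline = baseline,
    posterior = posterior,
    delta = delta,
    delta_rounded = lapply(delta, round_half_away)),
    class = "sensitivity_report")
}

#' Univariate sensitivity analysis
#'
#' Clamps one variable to one state with probability 100% and reports, for
#' every other variable and state, the change in posterior probability
#' relative to the no-evidence marginals, in percentage points. Deltas are
#' returned both raw (`delta`) and rounded half-away-from-zero to integers
#' (`delta_rounded`), the precision report tables print at.
#'
#' @param net A validated [bn_network()] with CPTs.
#' @param variable Evidence variable.
#' @param state Asserted state.
#' @return A `sensitivity_report` with elements `label`, `evidence`,
#'   `baseline`, `posterior`, `delta`, `delta_rounded`.
#' @export
univariate_sensitivity <- function(net, variable, state) {
  make_sensitivity_report(net, stats::setNames(state, variable),
                          label = sprintf("%s %s 100%%", variable, state))
}

#' Multivariate sensitivity analysis
#'
#' As [univariate_sensitivity()] but with joint hard evidence on two or more
#' variables.
#'
#' @param net A validated [bn_network()] with CPTs.
#' @param evidence Named character vector with at least two entries, e.g.
#'   `c(EE = "high", DP = "high")`.
#' @return A `sensitivity_report`.
#' @export
multivariate_sensitivity <- function(net, evidence) {
  ev <- check_evidence(net, evidence)
  if (length(ev) < 2)
    stop_validation("multivariate sensitivity needs evidence on at least two variables")
  make_sensitivity_report(net, ev)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %s\n", x$label))
  vars <- setdiff(names(x$delta), names(x$evidence))
  m <- do.call(rbind, lapply(x$delta[vars], round, 2))
  colnames(m) <- paste0("delta_", colnames(m))
  print(m)
  invisible(x)
}

report_delta_row <- function(report, vars, rounded = TRUE) {
  src <- if (rounded) report$delta_rounded else report$delta
  out <- list()
  for (v in vars) {
    for (s in names(src[[v]])) {
      val <- if (v %in% names(report$evidence)) NA_real_ else src[[v]][[s]]
      out[[paste(v, s, sep = "_")]] <- val
    }
  }
  out
}

#' Full sensitivity sweep
#'
#' Runs every univariate scenario (each variable clamped to each of its
#' states) and, by default, the published multivariate scenario families:
#' every 2-, 3-, and 4-subset of the burnout/resilience variables with all
#' members clamped jointly to "low" and jointly to "high". Scenario-level
#' inference errors are collected, not raised.
#'
#' @param net A validated [bn_network()] with CPTs.
#' @param combination_vars Variables entering the multivariate subset
#'   families (default `EE`, `DP`, `PA`, `resilience`).
#' @param subset_sizes Sizes of the evidence subsets (default `2:4`).
#' @param rounded Round the tabulated deltas to integer percentage points?
#' @return List of class `sensitivity_sweep`: `univariate` and
#'   `multivariate` report lists, the tabulated `univariate_table` and
#'   `multivariate_table` data.frames, and `errors`.
#' @export
full_sensitivity_sweep <- function(net,
                                   combination_vars = c("EE", "DP", "PA", "resilience"),
                                   subset_sizes = 2:4,
                                   rounded = TRUE) {
  validate_network(net)
  vars <- names(net$variables)
  errors <- list()
  run <- function(fun) tryCatch(fun(), burnoutbn_error = function(e) e)

  uni <- list()
  for (v in vars) for (s in net$variables[[v]]) {
    r <- run(function() univariate_sensitivity(net, v, s))
    uni[[paste(v, s, sep = "_")]] <- r
  }
  multi <- list()
  combination_vars <- intersect(combination_vars, vars)
  for (k in subset_sizes) {
    if (k > length(combination_vars)) next
    subsets <- utils::combn(combination_vars, k, simplify = FALSE)
    for (sub in subsets) for (s in c("low", "high")) {
      ev <- stats::setNames(rep(s, length(sub)), sub)
      r <- run(function() multivariate_sensitivity(net, ev))
      multi[[paste(paste(sub, collapse = "+"), s, sep = "_")]] <- r
    }
  }
  is_err <- function(x) inherits(x, "condition")
  errors <- c(Filter(is_err, uni), Filter(is_err, multi))
  uni <- Filter(Negate(is_err), uni)
  multi <- Filter(Negate(is_err), multi)

  uni_table <- do.call(rbind, lapply(uni, function(r) {
    data.frame(variable = names(r$evidence), state = unname(r$evidence),
               report_delta_row(r, vars, rounded), check.names = FALSE)
  }))
  rownames(uni_table) <- NULL
  outcome_vars <- setdiff(vars, combination_vars)
  multi_table <- do.call(rbind, lapply(multi, function(r) {
    row <- data.frame(evidence = r$label,
                      report_delta_row(r, outcome_vars, rounded),
                      check.names = FALSE)
    row
  }))
  if (!is.null(multi_table)) rownames(multi_table) <- NULL
  structure(list(univariate = uni, multivariate = multi,
                 univariate_table = uni_table, multivariate_table = multi_table,
                 errors = errors, rounded = rounded),
            class = "sensitivity_sweep")
}

#' @export
print.sensitivity_sweep <- function(x, ...) {
  cat(sprintf("<sensitivity_sweep> %d univariate + %d multivariate scenarios (%d error(s))\n",
              length(x$univariate), length(x$multivariate), length(x$errors)))
  invisible(x)
}

#' Delta-p association measure
#'
#' `Delta-p = P(outcome = outcome_state | antecedent = antecedent_state)
#'          - P(outcome = outcome_state | antecedent = complement)`,
#' the classic contingency measure of how much knowing the antecedent's
#' state moves the outcome.
#'
#' @param net A validated [bn_network()] with CPTs.
#' @param outcome,outcome_state Outcome variable and state.
#' @param antecedent,antecedent_state Antecedent variable (binary) and state.
#' @return A number in `[-1, 1]`.
#' @export
delta_p <- function(net, outcome, outcome_state, antecedent, antecedent_state) {
  validate_network(net)
  if (length(net$variables[[antecedent]]) != 2)
    stop_validation("delta_p needs a binary antecedent (complement state must be unique)")
  if (outcome == antecedent)
    stop_validation("outcome and antecedent must differ")
  check_evidence(net, stats::setNames(antecedent_state, antecedent))
  prior <- infer_marginals(net)[[antecedent]]
  if (prior[antecedent_state] <= 0 || prior[antecedent_state] >= 1)
    stop_degenerate(sprintf(
      "antecedent '%s' is degenerate (prior P(%s) = %g); Delta-p is undefined",
      antecedent, antecedent_state, prior[antecedent_state]))
  complement <- setdiff(net$variables[[antecedent]], antecedent_state)
  p1 <- infer_marginals(net, stats::setNames(antecedent_state, antecedent))[[outcome]][outcome_state]
  p0 <- infer_marginals(net, stats::setNames(complement, antecedent))[[outcome]][outcome_state]
  unname(p1 - p0)
}

soi_distance <- function(p, q, metric) {
  switch(metric,
         max_abs = max(abs(p - q)),
         euclidean = sqrt(sum((p - q)^2)),
         hellinger = sqrt(sum((sqrt(p) - sqrt(q))^2)) / sqrt(2),
         stop_validation(sprintf("unknown strength-of-influence metric '%s'", metric)))
}

#' Strength of influence of one arc
#'
#' For each configuration of the child's *other* parents, measures the
#' distance between the child's conditional distributions with the parent in
#' its two states. Reports the unweighted mean over configurations
#' (`average`), the largest distance (`maximum`), and the mean weighted by
#' the model's joint probability of each co-parent configuration,
#' renormalized (`weighted`).
#'
#' @param net A validated [bn_network()] with CPTs.
#' @param parent,child An arc of the network; the parent must be binary.
#' @param metric `"max_abs"` (maximum absolute state-probability difference,
#'   default), `"euclidean"`, or `"hellinger"`.
#' @return List of class `influence_strength` with `parent`, `child`,
#'   `metric`, `average`, `maximum`, `weighted`, and the per-configuration
#'   table.
#' @export
strength_of_influence <- function(net, parent, child, metric = "max_abs") {
  validate_network(net)
  if (!is.character(metric) || length(metric) != 1 ||
      !metric %in% c("max_abs", "euclidean", "hellinger"))
    stop_validation(sprintf("unknown strength-of-influence metric '%s'",
                            paste(metric, collapse = ",")))
  if (!any(net$arcs$parent == parent & net$arcs$child == child))
    stop_validation(sprintf("no arc %s -> %s in the network", parent, child))
  cpt <- net$cpts[[child]]
  if (length(net$variables[[parent]]) != 2)
    stop_validation("strength_of_influence assumes a binary parent")
  co_parents <- setdiff(cpt$parents, parent)
  grid <- if (length(co_parents) == 0) {
    data.frame(row.names = 1)
  } else {
    expand.grid(net$variables[co_parents], stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  }
  pstates <- net$variables[[parent]]
  dist <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    config <- if (length(co_parents) == 0) character(0) else
      stats::setNames(as.character(grid[i, co_parents]), co_parents)
    p <- cpt_row(cpt, c(config, stats::setNames(pstates[1], parent)))
    q <- cpt_row(cpt, c(config, stats::setNames(pstates[2], parent)))
    dist[i] <- soi_distance(p, q, metric)
  }
  if (length(co_parents) == 0) {
    weights <- 1
  } else {
    jt <- joint_table(net)
    weights <- vapply(seq_len(nrow(grid)), function(i) {
      mask <- rep(TRUE, nrow(jt))
      for (v in co_parents) mask <- mask & jt[[v]] == grid[i, v]
      sum(jt$p[mask])
    }, numeric(1))
    weights <- weights / sum(weights)
  }
  per_config <- cbind(grid, distance = dist, weight = weights)
  structure(list(parent = parent, child = child, metric = metric,
                 average = mean(dist), maximum = max(dist),
                 weighted = sum(weights * dist),
                 per_config = per_config),
            class = "influence_strength")
}

#' @export
print.influence_strength <- function(x, ...) {
  cat(sprintf("<influence_strength> %s -> %s (%s): average %.3f, maximum %.3f, weighted %.3f\n",
              x$parent, x$child, x$metric, x$average, x$maximum, x$weighted))
  invisible(x)
}

#' Strength of influence for every arc
#'
#' @param net A validated [bn_network()] with CPTs.
#' @param metric Passed to [strength_of_influence()].
#' @return data.frame with columns `parent`, `child`, `average`, `maximum`,
#'   `weighted`; attribute `metric` records the distance used.
#' @export
strength_of_influence_table <- function(net, metric = "max_abs") {
  rows <- lapply(seq_len(nrow(net$arcs)), function(i) {
    s <- strength_of_influence(net, net$arcs$parent[i], net$arcs$child[i], metric)
    data.frame(parent = s$parent, child = s$child, average = s$average,
               maximum = s$maximum, weighted = s$weighted)
  })
  out <- do.call(rbind, rows)
  attr(out, "metric") <- metric
  out
}
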