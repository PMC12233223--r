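#' Conditional probability table for one node
#'
#' @param child Child variable name.
#' @param parents Character vector of parent names (order matters: it fixes
#'   the dimension order of `prob`).
#' @param prob Numeric array of conditional probabilities. The first
#'   dimension indexes the child's states; each further dimension indexes
#'   one parent's states, in `parents` order. A root node takes a plain
#'   numeric vector. Every conditional distribution (slice over the child
#'   dimension) must sum to 1 within 1e-9.
#' @param states Named list giving the state labels of the child and each
#'   parent; defaults to `c("low", "high")` for every variable.
#' @return Object of class `bn_cpt`.
#' @export
bn_cpt <- function(child, parents = character(), prob,
                   states = NULL) {
  vars <- c(child, parents)
  if (anyDuplicated(vars))
    stop_validation(sprintf("CPT for '%s': duplicated variable in child/parents", child))
  if (is.null(states)) states <- stats::setNames(rep(list(c("low", "high")), length(vars)), vars)
  missing_states <- setdiff(vars, names(states))
  if (length(missing_states) > 0)
    states[missing_states] <- rep(list(c("low", "high")), length(missing_states))
  sizes <- unname(vapply(states[vars], length, integer(1)))
  prob <- as.array(prob)
  if (length(dim(prob)) == 1L && length(vars) == 1L) dim(prob) <- sizes
  if (!identical(as.integer(dim(prob)), as.integer(sizes)))
    stop_validation(sprintf(
      "CPT for '%s': prob has dim (%s) but child+parents imply (%s)",
      child, paste(dim(prob), collapse = ","), paste(sizes, collapse = ",")))
  prob <- array(as.numeric(prob), dim = sizes)    # canonical attributes
  dimnames(prob) <- stats::setNames(states[vars], vars)
  if (any(!is.finite(prob)) || any(prob < 0) || any(prob > 1))
    stop_validation(sprintf("CPT for '%s': entries must be probabilities in [0, 1]", child))
  sums <- if (length(parents) == 0) sum(prob) else
    apply(prob, seq_along(vars)[-1], sum)
  bad <- which(abs(sums - 1) > 1e-9)
  if (length(bad) > 0)
    stop_validation(sprintf(
      "CPT for '%s': %d conditional distribution(s) do not sum to 1 (first deviation %.3g)",
      child, length(bad), max(abs(sums - 1))))
  structure(list(child = child, parents = parents,
                 states = states[vars], prob = prob),
            class = "bn_cpt")
}

#' Build a CPT from an explicit row table
#'
#' Convenience constructor for CPTs transcribed from printed tables: one row
#' per full parent-state configuration, with one probability column per
#' child state. Every configuration must appear exactly once; absent or
#' duplicated configurations are reported by name.
#'
#' @param child Child variable name.
#' @param parents Parent names in column order.
#' @param rows data.frame with one column per parent (state labels) and the
#'   probability columns named in `prob_cols`.
#' @param prob_cols Names of the probability columns, in child-state order.
#' @param states Optional state labels (default `c("low","high")` everywhere).
#' @return A [bn_cpt()].
#' @export
cpt_from_rows <- function(child, parents, rows,
                          prob_cols = c("p_low", "p_high"), states = NULL) {
  if (is.null(states)) states <- stats::setNames(
    rep(list(c("low", "high")), length(parents) + 1L), c(child, parents))
  child_states <- states[[child]]
  if (length(prob_cols) != length(child_states))
    stop_validation("prob_cols must match the number of child states")
  grid <- expand.grid(states[parents], stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  key <- function(df) do.call(paste, c(df[parents], sep = "|"))
  if (length(parents) == 0) {
    if (nrow(rows) != 1L) stop_validation("root CPT needs exactly one row")
    prob <- as.numeric(rows[1, prob_cols])
    return(bn_cpt(child, parents, prob, states))
  }
  have <- key(rows)
  want <- key(grid)
  if (anyDuplicated(have))
    stop_validation(sprintf("CPT for '%s': duplicated configuration(s): %s",
                            child, paste(unique(have[duplicated(have)]), collapse = "; ")))
  absent <- setdiff(want, have)
  if (length(absent) > 0)
    stop_validation(sprintf(
      "CPT for '%s': missing configuration(s) of (%s): %s",
      child, paste(parents, collapse = ", "), paste(absent, collapse = "; ")))
  extra <- setdiff(have, want)
  if (length(extra) > 0)
    stop_validation(sprintf("CPT for '%s': unknown configuration(s): %s",
                            child, paste(extra, collapse = "; ")))
  ord <- match(want, have)
  prob_mat <- t(as.matrix(rows[ord, prob_cols, drop = FALSE]))
  prob <- array(as.numeric(prob_mat),
                dim = c(length(child_states), vapply(states[parents], length, integer(1))))
  bn_cpt(child, parents, prob, states)
}

#' @export
print.bn_cpt <- function(x, ...) {
  if (length(x$parents) == 0)
    cat(sprintf("<bn_cpt> %s (root)\n", x$child))
  else
    cat(sprintf("<bn_cpt> %s | %s\n", x$child, paste(x$parents, collapse = ", ")))
  print(x$prob, ...)
  invisible(x)
}

# one conditional distribution: config is a named character vector of
# parent states
cpt_row <- function(cpt, config) {
  if (length(cpt$parents) == 0) return(as.numeric(cpt$prob))
  idx <- c(list(TRUE), as.list(config[cpt$parents]))
  as.numeric(do.call(`[`, c(list(cpt$prob), idx)))
}

#' Assemble a discrete Bayesian network
#'
#' @param variables Either a character vector of variable names (binary
#'   `low`/`high` states assumed) or a named list mapping name to its
#'   ordered state labels.
#' @param arcs data.frame (or 2-column matrix) with columns `parent`,
#'   `child`.
#' @param cpts Optional named list of [bn_cpt()] objects, one per variable.
#'   Networks without CPTs describe structure only (e.g. as learning input).
#' @param validate Run [validate_network()] on the result (default `TRUE`
#'   when CPTs are supplied)?
#' @return Object of class `bn_network`.
#' @export
bn_network <- function(variables, arcs, cpts = NULL, validate = !is.null(cpts)) {
  if (!is.list(variables)) {
    variables <- stats::setNames(rep(list(c("low", "high")), length(variables)),
                                 variables)
  }
  if (is.matrix(arcs)) arcs <- data.frame(parent = arcs[, 1], child = arcs[, 2])
  if (is.null(arcs)) arcs <- data.frame(parent = character(), child = character())
  arcs <- data.frame(parent = as.character(arcs$parent),
                     child = as.character(arcs$child),
                     stringsAsFactors = FALSE)
  if (!is.null(cpts)) names(cpts) <- vapply(cpts, `[[`, character(1), "child")
  net <- structure(list(variables = variables, arcs = arcs, cpts = cpts),
                   class = "bn_network")
  if (validate) validate_network(net) else net
}

bn_parents <- function(net, var) net$arcs$parent[net$arcs$child == var]
bn_children <- function(net, var) net$arcs$child[net$arcs$parent == var]
bn_roots <- function(net) setdiff(names(net$variables), unique(net$arcs$child))

# Kahn topological sort; returns NULL when the arc set has a cycle
topo_order <- function(net) {
  vars <- names(net$variables)
  indeg <- stats::setNames(integer(length(vars)), vars)
  tab <- table(net$arcs$child)
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  queue <- vars[indeg == 0]
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in bn_children(net, v)) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(vars)) NULL else order
}

#' Validate a Bayesian network
#'
#' Checks the full invariant set — unique variables, arcs between declared
#' variables, acyclicity, one CPT per variable, CPT parent sets matching the
#' arc set, state labels matching the variable declarations, and normalized
#' CPT rows — and reports *all* violations at once in a single validation
#' error.
#'
#' @param net A [bn_network()].
#' @return The network, invisibly, when valid.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "bn_network"))
  problems <- character(0)
  vars <- names(net$variables)
  if (anyDuplicated(vars))
    problems <- c(problems, "duplicated variable names")
  for (v in vars) {
    st <- net$variables[[v]]
    if (length(st) < 2 || anyDuplicated(st))
      problems <- c(problems, sprintf("variable '%s' needs >=2 unique states", v))
  }
  bad_ep <- unique(c(setdiff(net$arcs$parent, vars), setdiff(net$arcs$child, vars)))
  if (length(bad_ep) > 0)
    problems <- c(problems, sprintf("arc endpoint(s) not declared as variables: %s",
                                    paste(bad_ep, collapse = ", ")))
  if (anyDuplicated(paste(net$arcs$parent, net$arcs$child)))
    problems <- c(problems, "duplicated arcs")
  if (length(bad_ep) == 0 && is.null(topo_order(net)))
    problems <- c(problems, "arc set contains a directed cycle")
  if (!is.null(net$cpts)) {
    no_cpt <- setdiff(vars, names(net$cpts))
    if (length(no_cpt) > 0)
      problems <- c(problems, sprintf("no CPT for variable(s): %s",
                                      paste(no_cpt, collapse = ", ")))
    for (cpt in net$cpts) {
      v <- cpt$child
      if (!v %in% vars) {
        problems <- c(problems, sprintf("CPT for undeclared variable '%s'", v))
        next
      }
      if (!setequal(cpt$parents, bn_parents(net, v)))
        problems <- c(problems, sprintf(
          "CPT for '%s' conditions on (%s) but the arcs declare parents (%s)",
          v, paste(cpt$parents, collapse = ", "),
          paste(bn_parents(net, v), collapse = ", ")))
      if (!identical(cpt$states[[v]], net$variables[[v]]))
        problems <- c(problems, sprintf("CPT for '%s' uses mismatched state labels", v))
    }
  }
  if (length(problems) > 0)
    stop_validation(paste0("invalid network:\n", paste0("  - ", problems, collapse = "\n")))
  invisible(net)
}

#' @export
print.bn_network <- function(x, ...) {
  cat(sprintf("<bn_network> %d variables, %d arcs%s\n",
              length(x$variables), nrow(x$arcs),
              if (is.null(x$cpts)) " (structure only)" else ""))
  cat("  variables:", paste(names(x$variables), collapse = ", "), "\n")
  invisible(x)
}

#' Joint probability of a complete assignment
#'
#' The network factorization: the product over nodes of
#' `P(child state | parent states)`.
#'
#' @param net A validated [bn_network()] with CPTs.
#' @param assignment Named character vector assigning a state to *every*
#'   variable.
#' @return A probability.
#' @export
joint_probability <- function(net, assignment) {
  vars <- names(net$variables)
  missing <- setdiff(vars, names(assignment))
  if (length(missing) > 0)
    stop_validation(sprintf("assignment lacks variable(s): %s",
                            paste(missing, collapse = ", ")))
  for (v in vars) {
    if (!assignment[[v]] %in% net$variables[[v]])
      stop_validation(sprintf("'%s' is not a state of '%s'", assignment[[v]], v))
  }
  p <- 1
  for (cpt in net$cpts) {
    row <- cpt_row(cpt, assignment)
    p <- p * row[match(assignment[[cpt$child]], cpt$states[[cpt$child]])]
  }
  p
}
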