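# Exact inference: variable elimination over discrete factors, plus a
# brute-force enumeration oracle used for testing and for small-network
# utilities (full joint table).
#
# A factor is a list(vars, states, values): `values` is a numeric vector in
# canonical order — the first variable in `vars` varies fastest (column-major,
# matching expand.grid(states[vars])).

factor_new <- function(vars, states, values) {
  list(vars = vars, states = states[vars], values = as.numeric(values))
}

cpt_factor <- function(cpt) {
  factor_new(c(cpt$child, cpt$parents), cpt$states, as.vector(cpt$prob))
}

# linear (1-based) index of each row of `grid` into factor f's value vector
factor_index <- function(f, grid) {
  idx <- 0L
  mult <- 1L
  for (v in f$vars) {
    pos <- match(grid[[v]], f$states[[v]]) - 1L
    idx <- idx + pos * mult
    mult <- mult * length(f$states[[v]])
  }
  idx + 1L
}

factor_product <- function(f, g) {
  vars <- union(f$vars, g$vars)
  states <- c(f$states, g$states)
  states <- states[!duplicated(names(states))]
  grid <- expand.grid(states[vars], stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  factor_new(vars, states, f$values[factor_index(f, grid)] * g$values[factor_index(g, grid)])
}

factor_sum_out <- function(f, var) {
  keep <- setdiff(f$vars, var)
  if (length(keep) == 0)
    return(factor_new(character(0), list(), sum(f$values)))
  grid <- expand.grid(f$states[f$vars], stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- f$vars
  g <- factor_new(keep, f$states, numeric(prod(vapply(f$states[keep], length, integer(1)))))
  group <- factor_index(g, grid)
  vals <- rowsum(f$values, group)          # sorted by group id = canonical order
  g$values <- as.numeric(vals)
  g
}

# restrict a factor to var = state, dropping var
factor_reduce <- function(f, var, state) {
  if (!var %in% f$vars) return(f)
  grid <- expand.grid(f$states[f$vars], stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- f$vars
  keep_rows <- grid[[var]] == state
  keep <- setdiff(f$vars, var)
  factor_new(keep, f$states, f$values[keep_rows])
}

check_evidence <- function(net, evidence) {
  if (length(evidence) == 0) return(stats::setNames(character(0), character(0)))
  evidence <- unlist(evidence)
  vars <- names(evidence)
  if (is.null(vars) || any(vars == ""))
    stop_validation("evidence must be a named vector/list: c(variable = \"state\")")
  if (anyDuplicated(vars))
    stop_validation(sprintf("duplicated evidence on variable(s): %s",
                            paste(unique(vars[duplicated(vars)]), collapse = ", ")))
  unknown <- setdiff(vars, names(net$variables))
  if (length(unknown) > 0)
    stop_validation(sprintf("evidence on undeclared variable(s): %s",
                            paste(unknown, collapse = ", ")))
  for (v in vars) {
    if (!evidence[[v]] %in% net$variables[[v]])
      stop_validation(sprintf("'%s' is not a state of '%s'", evidence[[v]], v))
  }
  evidence
}

# minimum-degree elimination order over the moral graph, restricted to `elim`
elimination_order <- function(net, elim) {
  vars <- names(net$variables)
  adj <- matrix(FALSE, length(vars), length(vars), dimnames = list(vars, vars))
  for (cpt in net$cpts) {
    clique <- c(cpt$child, cpt$parents)
    adj[clique, clique] <- TRUE
  }
  diag(adj) <- FALSE
  order <- character(0)
  remaining <- elim
  active <- vars
  while (length(remaining) > 0) {
    deg <- vapply(remaining, function(v) sum(adj[v, active]), numeric(1))
    v <- remaining[which.min(deg)]
    nb <- active[adj[v, active]]
    if (length(nb) > 1) adj[nb, nb] <- TRUE   # fill-in
    diag(adj) <- FALSE
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
    active <- setdiff(active, v)
  }
  order
}

ve_eliminate <- function(factors, order) {
  for (v in order) {
    has_v <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(has_v)) next
    prod_f <- Reduce(factor_product, factors[has_v])
    factors <- c(factors[!has_v], list(factor_sum_out(prod_f, v)))
  }
  factors
}

#' Posterior marginals by variable elimination
#'
#' Exact inference with hard evidence: every evidence variable is clamped to
#' its asserted state with probability 1, and the posterior marginal of every
#' other variable is computed by sum-product variable elimination
#' (minimum-degree elimination order on the moral graph). Probabilities are
#' kept in linear space; with the package's six-binary-node study network no
#' intermediate factor can underflow.
#'
#' @param net A validated [bn_network()] with CPTs.
#' @param evidence Named character vector of hard evidence, e.g.
#'   `c(EE = "high")`; empty for prior marginals.
#' @return Named list of per-variable state distributions (class
#'   `bn_marginals`), each normalized; evidenced variables carry probability
#'   1 on the asserted state. Attribute `p_evidence` holds the evidence
#'   probability.
#' @export
infer_marginals <- function(net, evidence = character(0)) {
  validate_network(net)
  evidence <- check_evidence(net, evidence)
  vars <- names(net$variables)
  base_factors <- lapply(net$cpts, cpt_factor)
  for (v in names(evidence))
    base_factors <- lapply(base_factors, factor_reduce, var = v, state = evidence[[v]])
  free <- setdiff(vars, names(evidence))
  out <- vector("list", length(vars))
  names(out) <- vars
  p_evidence <- NA_real_
  for (q in free) {
    order <- elimination_order(net, setdiff(free, q))
    fs <- ve_eliminate(base_factors, order)
    final <- Reduce(factor_product, fs)
    # `final` has vars = q (constants were absorbed by the product)
    vals <- if (identical(final$vars, q)) final$values else {
      g <- factor_new(q, net$variables[q], numeric(length(net$variables[[q]])))
      grid <- expand.grid(final$states[final$vars], stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      names(grid) <- final$vars
      as.numeric(rowsum(final$values, factor_index(g, grid)))
    }
    z <- sum(vals)
    if (z <= 0)
      stop_inconsistent_evidence(sprintf(
        "evidence {%s} has probability zero under the model",
        paste(names(evidence), evidence, sep = "=", collapse = ", ")))
    p_evidence <- z
    out[[q]] <- stats::setNames(vals / z, net$variables[[q]])
  }
  if (length(free) == 0) {
    # all variables evidenced: evidence probability via the joint
    p_evidence <- joint_probability(net, evidence)
    if (p_evidence <= 0)
      stop_inconsistent_evidence(sprintf(
        "evidence {%s} has probability zero under the model",
        paste(names(evidence), evidence, sep = "=", collapse = ", ")))
  }
  for (v in names(evidence)) {
    d <- stats::setNames(rep(0, length(net$variables[[v]])), net$variables[[v]])
    d[evidence[[v]]] <- 1
    out[[v]] <- d
  }
  structure(out, class = "bn_marginals", evidence = evidence, p_evidence = p_evidence)
}

#' @export
print.bn_marginals <- function(x, digits = 4, ...) {
  ev <- attr(x, "evidence")
  if (length(ev) > 0)
    cat("posterior marginals given",
        paste(names(ev), ev, sep = "=", collapse = ", "), "\n")
  else cat("prior marginals\n")
  m <- do.call(rbind, lapply(x, function(d) round(d, digits)))
  print(m)
  invisible(x)
}

#' Full joint distribution table
#'
#' Every complete assignment with its joint probability; intended for small
#' networks (at most 20 binary variables).
#'
#' @param net A validated [bn_network()] with CPTs.
#' @return data.frame with one state column per variable plus `p`.
#' @export
joint_table <- function(net) {
  vars <- names(net$variables)
  if (prod(vapply(net$variables, length, integer(1))) > 2^20)
    stop_validation("joint_table is limited to ~2^20 assignments")
  grid <- expand.grid(net$variables, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  p <- rep(1, nrow(grid))
  for (cpt in net$cpts) {
    cols <- as.matrix(grid[c(cpt$child, cpt$parents)])
    p <- p * cpt$prob[cols]        # character-matrix indexing via dimnames
  }
  grid$p <- p
  grid
}

#' Brute-force marginals by exhaustive enumeration
#'
#' Reference oracle for [infer_marginals()]: sums the joint probability over
#' all assignments consistent with the evidence and normalizes. Limited to
#' networks whose state space enumerates comfortably (~20 binary variables).
#'
#' @inheritParams infer_marginals
#' @return A `bn_marginals` object.
#' @export
enumerate_marginals <- function(net, evidence = character(0)) {
  validate_network(net)
  evidence <- check_evidence(net, evidence)
  jt <- joint_table(net)
  mask <- rep(TRUE, nrow(jt))
  for (v in names(evidence)) mask <- mask & jt[[v]] == evidence[[v]]
  z <- sum(jt$p[mask])
  if (z <= 0)
    stop_inconsistent_evidence(sprintf(
      "evidence {%s} has probability zero under the model",
      paste(names(evidence), evidence, sep = "=", collapse = ", ")))
  out <- lapply(names(net$variables), function(v) {
    tapply_states <- vapply(net$variables[[v]], function(s)
      sum(jt$p[mask & jt[[v]] == s]), numeric(1))
    tapply_states / z
  })
  names(out) <- names(net$variables)
  structure(out, class = "bn_marginals", evidence = evidence, p_evidence = z)
}
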