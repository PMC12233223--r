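#' Settings for CPT estimation
#'
#' @param tolerance Convergence tolerance on the change in observed-data
#'   log-likelihood between EM iterations.
#' @param max_iterations Maximum number of EM iterations.
#' @param fallback Distribution assigned to parent configurations with no
#'   (expected) observations; only `"uniform"` is provided, matching the
#'   0.50/0.50 rows seen in crosstab-estimated tables.
#' @param pseudocount Optional Laplace pseudocount added to every cell
#'   before normalization (default 0).
#' @param init EM initialization: `"uniform"` (deterministic, default),
#'   `"random"` (seeded random rows), or `"cpts"` (start from `init_cpts`).
#' @param init_cpts Named list of [bn_cpt()]s used when `init = "cpts"`.
#' @param seed Seed for random initialization.
#' @return A `learn_settings` list.
#' @export
learn_settings <- function(tolerance = 1e-6, max_iterations = 500,
                           fallback = "uniform", pseudocount = 0,
                           init = c("uniform", "random", "cpts"),
                           init_cpts = NULL, seed = NULL) {
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop_validation("tolerance must be positive")
  if (!is_whole(max_iterations) || max_iterations < 1)
    stop_validation("max_iterations must be a positive integer")
  if (!is.numeric(pseudocount) || pseudocount < 0)
    stop_validation("pseudocount must be non-negative")
  fallback <- match.arg(fallback, "uniform")
  structure(list(tolerance = tolerance, max_iterations = as.integer(max_iterations),
                 fallback = fallback, pseudocount = pseudocount,
                 init = match.arg(init), init_cpts = init_cpts, seed = seed),
            class = "learn_settings")
}

check_records <- function(records, net, allow_missing = TRUE) {
  vars <- names(net$variables)
  missing_cols <- setdiff(vars, names(records))
  if (length(missing_cols) > 0)
    stop_validation(sprintf("records lack variable column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  if (nrow(records) == 0)
    stop_validation("empty record set")
  for (v in vars) {
    x <- records[[v]]
    if (!allow_missing && anyNA(x))
      stop_validation(sprintf("variable '%s' has missing cells; complete data required", v))
    bad <- setdiff(unique(x[!is.na(x)]), net$variables[[v]])
    if (length(bad) > 0)
      stop_validation(sprintf("variable '%s' has undeclared state(s): %s",
                              v, paste(bad, collapse = ", ")))
  }
  records[vars]
}

# normalize a (child x parent-config) count array into a CPT prob array;
# zero-total configurations fall back to the uniform distribution
normalize_counts <- function(counts, pseudocount) {
  d <- dim(counts)
  counts <- counts + pseudocount
  m <- matrix(counts, nrow = d[1])
  totals <- colSums(m)
  zero <- totals <= 0
  m[, zero] <- 1 / d[1]
  totals[zero] <- 1
  prob <- sweep(m, 2, totals, "/")
  array(prob, dim = d)
}

#' Maximum-likelihood CPTs from complete records (crosstab estimation)
#'
#' Each CPT row is the conditional relative frequency of the child's states
#' among records matching that parent configuration — exactly a crosstab of
#' the child against its parents. Configurations with no matching records
#' receive the uniform fallback distribution (or pseudocount-smoothed
#' frequencies when `pseudocount > 0`).
#'
#' @param records data.frame of state labels, one column per variable, no
#'   missing cells.
#' @param structure A [bn_network()] (CPTs, if present, are ignored).
#' @param pseudocount Laplace pseudocount added to every cell (default 0).
#' @return A validated [bn_network()] with the learned CPTs; attribute
#'   `unobserved_configs` counts fallback rows per variable.
#' @export
mle_cpts <- function(records, structure, pseudocount = 0) {
  records <- check_records(records, structure, allow_missing = FALSE)
  vars <- names(structure$variables)
  unobserved <- stats::setNames(integer(length(vars)), vars)
  cpts <- lapply(vars, function(v) {
    parents <- bn_parents(structure, v)
    fs <- lapply(c(v, parents), function(u)
      factor(records[[u]], levels = structure$variables[[u]]))
    counts <- do.call(table, fs)
    counts <- array(as.numeric(counts), dim = dim(counts) %||% length(counts))
    totals <- if (length(parents) == 0) sum(counts) else colSums(matrix(counts, nrow = dim(counts)[1]))
    unobserved[[v]] <<- sum(totals + pseudocount * dim(counts)[1] <= 0)
    bn_cpt(v, parents, normalize_counts(counts, pseudocount),
           structure$variables[c(v, parents)])
  })
  net <- bn_network(structure$variables, structure$arcs, cpts)
  attr(net, "unobserved_configs") <- unobserved
  net
}

init_em_cpts <- function(structure, settings) {
  vars <- names(structure$variables)
  if (settings$init == "cpts") {
    if (is.null(settings$init_cpts))
      stop_validation("init = 'cpts' needs init_cpts")
    return(settings$init_cpts[vars])
  }
  make <- function(v) {
    parents <- bn_parents(structure, v)
    sizes <- vapply(structure$variables[c(v, parents)], length, integer(1))
    n <- prod(sizes)
    prob <- if (settings$init == "uniform") {
      array(1 / sizes[1], dim = sizes)
    } else {
      raw <- matrix(stats::runif(n, 0.1, 1), nrow = sizes[1])
      array(sweep(raw, 2, colSums(raw), "/"), dim = sizes)
    }
    bn_cpt(v, parents, prob, structure$variables[c(v, parents)])
  }
  if (settings$init == "random" && !is.null(settings$seed))
    withr::with_seed(settings$seed, lapply(vars, make))
  else
    lapply(vars, make)
}

#' EM estimation of CPTs from records with missing cells
#'
#' Expectation-maximization for ignorable (MCAR/MAR) missingness: the E-step
#' distributes each incomplete record over its completions in proportion to
#' their joint probability under the current parameters (exact — computed by
#' enumerating the joint state space, which is feasible for the small
#' networks this package targets), and the M-step re-estimates every CPT row
#' from the expected counts. The observed-data log-likelihood is
#' non-decreasing across iterations; iteration stops when its improvement
#' drops below `settings$tolerance` or at `settings$max_iterations`.
#'
#' On complete data the E-step is degenerate and the result equals
#' [mle_cpts()] after the first iteration.
#'
#' @param records data.frame of state labels; `NA` cells are missing. Every
#'   variable must be observed at least once.
#' @param structure A [bn_network()] giving the DAG.
#' @param settings A [learn_settings()].
#' @return List of class `em_result`: `network` (learned CPTs), `log`
#'   (data.frame of iteration and observed-data log-likelihood), `converged`
#'   flag, and `iterations`.
#' @export
em_learn <- function(records, structure, settings = learn_settings()) {
  records <- check_records(records, structure, allow_missing = TRUE)
  vars <- names(structure$variables)
  n_states <- prod(vapply(structure$variables, length, integer(1)))
  if (n_states > 2^16)
    stop_validation("em_learn enumerates the joint state space; limited to ~16 binary variables")
  cpts <- init_em_cpts(structure, settings)
  names(cpts) <- vars

  grid <- expand.grid(structure$variables, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  gm <- as.matrix(grid)
  # canonical count-array index of each joint assignment, per variable
  lin_idx <- lapply(vars, function(v) {
    parents <- bn_parents(structure, v)
    f <- factor_new(c(v, parents), structure$variables, numeric(0))
    factor_index(f, grid)
  })
  names(lin_idx) <- vars
  sizes <- lapply(vars, function(v) {
    parents <- bn_parents(structure, v)
    vapply(structure$variables[c(v, parents)], length, integer(1))
  })
  names(sizes) <- vars

  # group identical observed patterns so the E-step runs once per pattern
  keys <- do.call(paste, c(lapply(records, function(x) ifelse(is.na(x), ".", x)),
                           sep = "\r"))
  pat_count <- table(keys)
  pat_rows <- records[match(names(pat_count), keys), , drop = FALSE]
  masks <- lapply(seq_len(nrow(pat_rows)), function(i) {
    m <- rep(TRUE, nrow(gm))
    for (v in vars) {
      val <- pat_rows[i, v]
      if (!is.na(val)) m <- m & gm[, v] == val
    }
    which(m)
  })
  counts <- as.numeric(pat_count)

  log_iter <- numeric(0)
  converged <- FALSE
  ll_prev <- -Inf
  iter <- 0
  while (iter < settings$max_iterations) {
    iter <- iter + 1
    p_jt <- rep(1, nrow(gm))
    for (cpt in cpts)
      p_jt <- p_jt * cpt$prob[gm[, c(cpt$child, cpt$parents), drop = FALSE]]
    wtot <- numeric(nrow(gm))
    ll <- 0
    for (i in seq_along(masks)) {
      rows <- masks[[i]]
      s <- sum(p_jt[rows])
      if (s <= 0)
        stop_inconsistent_evidence(
          "a record pattern has probability zero under the current parameters")
      ll <- ll + counts[i] * log(s)
      wtot[rows] <- wtot[rows] + counts[i] * p_jt[rows] / s
    }
    log_iter <- c(log_iter, ll)
    if (is.finite(ll_prev) && ll - ll_prev < settings$tolerance) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # M-step
    cpts <- lapply(vars, function(v) {
      cnt <- array(as.numeric(rowsum(wtot, lin_idx[[v]])), dim = sizes[[v]])
      bn_cpt(v, bn_parents(structure, v),
             normalize_counts(cnt, settings$pseudocount),
             structure$variables[c(v, bn_parents(structure, v))])
    })
    names(cpts) <- vars
  }
  net <- bn_network(structure$variables, structure$arcs, cpts)
  structure(list(network = net,
                 log = data.frame(iteration = seq_along(log_iter),
                                  loglik = log_iter),
                 converged = converged, iterations = length(log_iter)),
            class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf("<em_result> %d iteration(s), %s (final loglik %.4f)\n",
              x$iterations,
              if (x$converged) "converged" else "NOT converged",
              utils::tail(x$log$loglik, 1)))
  invisible(x)
}
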