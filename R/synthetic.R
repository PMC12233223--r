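# Synthetic survey generator: forward-samples binary states from a network,
# then materializes item-level questionnaire responses consistent with those
# states, so the full scoring -> dichotomization -> learning -> validation
# pipeline can be exercised without confidential respondent data.

#' Default dichotomization thresholds used by the generator
#'
#' Mid-range cut points, one per raw construct, chosen inside each
#' instrument's achievable score range (EE 0-54, DP 0-30, PA 0-48,
#' CD-RISC 0-100, compliance 12-60, participation 11-55).
#'
#' @return Named numeric vector of thresholds.
#' @export
default_thresholds <- function() {
  c(EE = 27, DP = 15, PA_raw = 24, resilience_raw = 50,
    compliance_raw = 36, participation_raw = 33)
}

#' Synthetic cohort generator configuration
#'
#' The defaults emulate the study conditions: 200 respondents sampled from
#' the packaged study network (published root marginals and participation
#' CPT; synthetic resilience/compliance CPTs), no missingness, no item
#' noise.
#'
#' @param model Generating [bn_network()].
#' @param n Number of respondents.
#' @param missing_rate MCAR blanking probability per state cell, in `[0, 1)`.
#' @param noise Per-item jitter probability in `[0, 1)` (each affected item
#'   moves by one scale point, clipped to the item range).
#' @param thresholds Named raw-score thresholds (see [default_thresholds()]).
#' @param seed Integer seed; every downstream draw derives from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(model = study_network(), n = 200,
                             missing_rate = 0, noise = 0,
                             thresholds = default_thresholds(), seed = 1) {
  validate_network(model)
  if (!is_whole(n) || n < 1) stop_validation("n must be a positive integer")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_validation("missing_rate must be in [0, 1)")
  if (noise < 0 || noise >= 1)
    stop_validation("noise must be in [0, 1)")
  structure(list(model = model, n = as.integer(n),
                 missing_rate = missing_rate, noise = noise,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "generator_config")
}

#' Forward-sample state records from a network
#'
#' Ancestral sampling: variables are visited in topological order and each
#' is drawn from its CPT row given its parents' sampled states.
#' Deterministic given the seed.
#'
#' @param net A validated [bn_network()] with CPTs.
#' @param n Number of records.
#' @param seed Integer seed.
#' @return data.frame of state labels, one column per variable.
#' @export
sample_states <- function(net, n, seed = 1) {
  validate_network(net)
  order <- topo_order(net)
  withr::with_seed(as.integer(seed), {
    out <- as.data.frame(stats::setNames(
      rep(list(character(n)), length(order)), order))
    for (v in order) {
      cpt <- net$cpts[[v]]
      states <- net$variables[[v]]
      if (length(cpt$parents) == 0) {
        probs <- matrix(as.numeric(cpt$prob), nrow = n, ncol = length(states),
                        byrow = TRUE)
      } else {
        probs <- vapply(states, function(s) {
          ix <- cbind(s, as.matrix(out[, cpt$parents, drop = FALSE]))
          as.numeric(cpt$prob[ix])
        }, numeric(n))
        if (n == 1) probs <- matrix(probs, nrow = 1)
      }
      u <- stats::runif(n)
      cum <- probs %*% upper.tri(diag(length(states)), diag = TRUE)
      out[[v]] <- states[rowSums(u > cum) + 1L]
    }
    out[names(net$variables)]
  })
}

# admissible integer raw-score range for a construct given its model state
score_range_for_state <- function(state, threshold, high_when, lo, hi) {
  if (high_when == "above") {
    if (state == "high") c(floor(threshold) + 1, hi) else c(lo, floor(threshold))
  } else {
    if (state == "high") c(lo, ceiling(threshold) - 1) else c(ceiling(threshold), hi)
  }
}

# random composition of `total` over k items each bounded in [lo, hi]
bounded_composition <- function(total, k, lo, hi) {
  out <- integer(k)
  rem <- total
  for (i in seq_len(k)) {
    left <- k - i
    lo_i <- max(lo, rem - left * hi)
    hi_i <- min(hi, rem - left * lo)
    out[i] <- if (lo_i >= hi_i) lo_i else lo_i + sample.int(hi_i - lo_i + 1L, 1L) - 1L
    rem <- rem - out[i]
  }
  out
}

#' Materialize item responses consistent with binary model states
#'
#' For each respondent and construct, a raw construct score is drawn
#' uniformly from the integer sub-range on the correct side of that
#' construct's threshold (respecting its score direction), then partitioned
#' across the construct's items by a random composition within the per-item
#' bounds. With `noise = 0` the round trip through [score_survey()] and
#' [dichotomize()] (at the same thresholds) reproduces the states exactly;
#' with `noise > 0` each item is independently jittered by one scale point
#' with that probability.
#'
#' @param states data.frame of model-variable states from [sample_states()].
#' @param specs Instrument list from [default_instrument_specs()].
#' @param thresholds Named raw-construct thresholds.
#' @param noise Per-item jitter probability.
#' @param seed Integer seed.
#' @return List: `items` (data.frame `mbi_01..sb_23`) and `raw_scores`
#'   (the construct scores the generator targeted).
#' @export
states_to_items <- function(states, specs = default_instrument_specs(),
                            thresholds = default_thresholds(), noise = 0,
                            seed = 1) {
  ctab <- construct_table()
  layout <- list(
    EE = list(spec = specs$mbi, prefix = "mbi", items = specs$mbi$subscales$EE),
    DP = list(spec = specs$mbi, prefix = "mbi", items = specs$mbi$subscales$DP),
    PA_raw = list(spec = specs$mbi, prefix = "mbi", items = specs$mbi$subscales$PA_raw),
    resilience_raw = list(spec = specs$cdrisc, prefix = "cd",
                          items = seq_len(specs$cdrisc$item_count)),
    compliance_raw = list(spec = specs$safety, prefix = "sb",
                          items = specs$safety$subscales$compliance_raw),
    participation_raw = list(spec = specs$safety, prefix = "sb",
                             items = specs$safety$subscales$participation_raw))
  n <- nrow(states)
  # feasibility: both state ranges must be non-empty
  for (con in names(layout)) {
    l <- layout[[con]]
    lo <- l$spec$item_range[1] * length(l$items)
    hi <- l$spec$item_range[2] * length(l$items)
    thr <- thresholds[[con]]
    if (is.null(thr) || is.na(thr))
      stop_validation(sprintf("no threshold for construct '%s'", con))
    hw <- ctab$high_when[ctab$construct == con]
    for (s in c("low", "high")) {
      r <- score_range_for_state(s, thr, hw, lo, hi)
      if (r[1] > r[2])
        stop_validation(sprintf(
          "threshold %g for '%s' leaves no achievable score for the %s state (range %d-%d)",
          thr, con, s, lo, hi))
    }
  }
  withr::with_seed(as.integer(seed), {
    cols <- list(
      mbi = matrix(0L, n, specs$mbi$item_count),
      cd = matrix(0L, n, specs$cdrisc$item_count),
      sb = matrix(0L, n, specs$safety$item_count))
    raw <- as.data.frame(stats::setNames(rep(list(numeric(n)), length(layout)),
                                         names(layout)))
    for (con in names(layout)) {
      l <- layout[[con]]
      rng <- l$spec$item_range
      hw <- ctab$high_when[ctab$construct == con]
      var <- ctab$variable[ctab$construct == con]
      for (i in seq_len(n)) {
        r <- score_range_for_state(states[i, var], thresholds[[con]], hw,
                                   rng[1] * length(l$items), rng[2] * length(l$items))
        total <- r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
        raw[i, con] <- total
        cols[[l$prefix]][i, l$items] <- bounded_composition(total, length(l$items),
                                                            rng[1], rng[2])
      }
    }
    if (noise > 0) {
      for (pre in names(cols)) {
        m <- cols[[pre]]
        rng <- switch(pre, mbi = specs$mbi$item_range, cd = specs$cdrisc$item_range,
                      sb = specs$safety$item_range)
        hit <- matrix(stats::runif(length(m)) < noise, nrow = n)
        step <- matrix(sample(c(-1L, 1L), length(m), replace = TRUE), nrow = n)
        m[hit] <- pmin(pmax(m[hit] + step[hit], rng[1]), rng[2])
        cols[[pre]] <- m
      }
    }
    items <- data.frame(
      stats::setNames(as.data.frame(cols$mbi), sprintf("mbi_%02d", 1:ncol(cols$mbi))),
      stats::setNames(as.data.frame(cols$cd), sprintf("cd_%02d", 1:ncol(cols$cd))),
      stats::setNames(as.data.frame(cols$sb), sprintf("sb_%02d", 1:ncol(cols$sb))))
    list(items = items, raw_scores = raw)
  })
}

#' Blank cells completely at random
#'
#' Each cell of the non-`id` columns is independently set to `NA` with
#' probability `rate` (MCAR); deterministic given the seed.
#'
#' @param table data.frame.
#' @param rate Blanking probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The table with blanks.
#' @export
inject_missingness <- function(table, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop_validation("rate must be in [0, 1)")
  if (rate == 0) return(table)
  cols <- setdiff(names(table), "id")
  withr::with_seed(as.integer(seed), {
    for (v in cols) {
      blank <- stats::runif(nrow(table)) < rate
      table[[v]][blank] <- NA
    }
  })
  table
}

#' Simulate a full synthetic survey cohort
#'
#' Samples ground-truth binary states from the configured network, generates
#' consistent item-level responses, and (optionally) blanks state cells
#' completely at random for EM testing.
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_cohort`: `items` (item-level survey
#'   table with `id`), `states` (ground truth with `id`), `states_observed`
#'   (after MCAR blanking; equal to `states` when `missing_rate = 0`),
#'   `raw_scores`, `model`, `thresholds`, `seed`.
#' @export
simulate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  states <- sample_states(config$model, config$n, derive_seed(config$seed, 1L))
  gen <- states_to_items(states, default_instrument_specs(), config$thresholds,
                         config$noise, derive_seed(config$seed, 2L))
  states_id <- cbind(id = seq_len(config$n), states)
  observed <- if (config$missing_rate > 0) {
    inject_missingness(states_id, config$missing_rate, derive_seed(config$seed, 3L))
  } else states_id
  structure(list(items = cbind(id = seq_len(config$n), gen$items),
                 states = states_id,
                 states_observed = observed,
                 raw_scores = gen$raw_scores,
                 model = config$model,
                 thresholds = config$thresholds,
                 seed = config$seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d respondents, %d item columns (seed %d)\n",
              nrow(x$items), ncol(x$items) - 1L, x$seed))
  invisible(x)
}

#' Recover model states from a cohort's item responses
#'
#' Scores the cohort's item table and dichotomizes at the generator's own
#' thresholds; with zero item noise this reproduces the ground-truth states
#' exactly.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return data.frame of recovered states (same shape as `cohort$states`).
#' @export
recover_states <- function(cohort) {
  scores <- score_survey(cohort$items)
  dichotomize(scores, dichotomization_rules(cohort$thresholds))
}
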