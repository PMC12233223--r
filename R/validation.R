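# Predictive validation: k-fold cross-validation of the fitted network and
# ROC analysis of the held-out predictions.

#' Random fold assignment for k-fold cross-validation
#'
#' Seeded uniform random partition into `k` folds whose sizes differ by at
#' most one; deterministic given the seed.
#'
#' @param n Number of records.
#' @param k Number of folds (study default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`, one per record.
#' @export
make_folds <- function(n, k = 10, seed = 1) {
  if (!is_whole(n) || !is_whole(k) || k < 2)
    stop_validation("make_folds needs integer n and k >= 2")
  if (k > n)
    stop_validation(sprintf("cannot split %d records into %d folds", n, k))
  withr::with_seed(as.integer(seed), sample(rep_len(seq_len(k), n)))
}

#' Cross-validated predictions from the Bayesian network
#'
#' For each fold, CPTs are learned on the remaining folds ([mle_cpts()] on
#' complete data, [em_learn()] when missing cells are present) and each
#' held-out record's probability of the target variable's "high" state is
#' predicted by exact inference, using the record's other observed variables
#' as hard evidence. Training folds that leave a parent configuration
#' unobserved fall back to uniform CPT rows (or pseudocount smoothing via
#' `settings`); held-out records whose evidence is impossible under the
#' trained model are scored with the trained prior of the target and noted.
#'
#' @param records data.frame of state labels over the network variables
#'   (`NA` = missing).
#' @param structure A [bn_network()] giving the DAG.
#' @param target Predicted variable; defaults to the terminal
#'   `"participation"` node.
#' @param settings A [learn_settings()] used for (EM) learning.
#' @param folds Fold assignment from [make_folds()]; built from `k` and
#'   `seed` when omitted.
#' @param k,seed Used when `folds` is `NULL`.
#' @return data.frame of class `prediction_set` with columns `id`, `fold`,
#'   `truth`, `prob_high`; attributes `target` and `notes`.
#' @export
cross_validate <- function(records, structure, target = "participation",
                           settings = learn_settings(), folds = NULL,
                           k = 10, seed = 1) {
  recs <- check_records(records, structure, allow_missing = TRUE)
  vars <- names(structure$variables)
  if (!target %in% vars)
    stop_validation(sprintf("target '%s' is not a network variable", target))
  if (length(structure$variables[[target]]) != 2)
    stop_validation("cross_validate expects a binary target")
  if (anyNA(recs[[target]]))
    stop_validation("target variable must be observed for every record")
  folds <- folds %||% make_folds(nrow(recs), k, seed)
  if (length(folds) != nrow(recs))
    stop_validation("fold assignment length must match the record count")
  notes <- character(0)
  models <- list()
  preds <- data.frame(id = seq_len(nrow(recs)), fold = folds,
                      truth = recs[[target]], prob_high = NA_real_)
  for (f in sort(unique(folds))) {
    train <- recs[folds != f, , drop = FALSE]
    fitted <- if (anyNA(train)) {
      em_learn(train, structure, settings)$network
    } else {
      mle_cpts(train, structure, pseudocount = settings$pseudocount)
    }
    unobs <- attr(fitted, "unobserved_configs")
    if (!is.null(unobs) && sum(unobs) > 0)
      notes <- c(notes, sprintf(
        "fold %d: %d unobserved parent configuration(s) received the fallback distribution",
        f, sum(unobs)))
    models[[as.character(f)]] <- fitted
    prior <- infer_marginals(fitted)[[target]][["high"]]
    test_idx <- which(folds == f)
    for (i in test_idx) {
      row <- unlist(recs[i, setdiff(vars, target), drop = FALSE])
      ev <- row[!is.na(row)]
      p <- tryCatch(
        infer_marginals(fitted, ev)[[target]][["high"]],
        inconsistent_evidence_error = function(e) {
          notes <<- c(notes, sprintf(
            "record %d: evidence impossible under fold-%d model; used trained prior", i, f))
          prior
        })
      preds$prob_high[i] <- p
    }
  }
  structure(preds, class = c("prediction_set", "data.frame"),
            target = target, notes = notes, models = models)
}

#' ROC curve and AUC from prediction scores
#'
#' Sweeps the decision threshold over the unique scores (ties grouped into a
#' single step), accumulating true/false positive rates, and integrates the
#' area under the curve by the trapezoidal rule. The curve starts at (0,0)
#' and ends at (1,1).
#'
#' @param scores Numeric vector of predicted probabilities of the positive
#'   state (or a `prediction_set` from [cross_validate()], in which case
#'   `truth` is taken from it).
#' @param truth Character/factor vector of true states.
#' @param positive Label of the positive class (default `"high"`).
#' @return List of class `roc_result`: `points` (data.frame `threshold`,
#'   `fpr`, `tpr`), `auc`, and `youden` (the threshold maximizing
#'   sensitivity + specificity - 1).
#' @export
roc_curve <- function(scores, truth = NULL, positive = "high") {
  if (inherits(scores, "prediction_set")) {
    truth <- scores$truth
    scores <- scores$prob_high
  }
  if (length(scores) != length(truth))
    stop_validation("scores and truth must have equal length")
  pos <- truth == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop_degenerate("ROC needs both classes present among the true states")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores into one step
  steps <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(p)[steps]
  fp <- cumsum(!p)[steps]
  points <- data.frame(threshold = c(Inf, s[steps]),
                       fpr = c(0, fp / n_neg),
                       tpr = c(0, tp / n_pos))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  youden_ix <- which.max(points$tpr - points$fpr)
  structure(list(points = points, auc = auc,
                 youden = points$threshold[youden_ix],
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, digits = 3, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d positives, %d negatives); Youden threshold %s\n",
              x$auc, x$n_pos, x$n_neg, format(x$youden, digits = digits)))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x A `roc_result`.
#' @param ... Passed to [plot()].
#' @export
plot.roc_result <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Confusion-matrix metrics at a decision threshold
#'
#' Predicts the positive state when the score is at least `threshold`
#' (default 0.5) and reports sensitivity (true-positive rate), specificity
#' (true-negative rate), and accuracy.
#'
#' @inheritParams roc_curve
#' @param threshold Decision threshold on the score.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`.
#' @export
classification_metrics <- function(scores, truth = NULL, threshold = 0.5,
                                   positive = "high") {
  if (inherits(scores, "prediction_set")) {
    truth <- scores$truth
    scores <- scores$prob_high
  }
  pos <- truth == positive
  if (sum(pos) == 0 || sum(!pos) == 0)
    stop_degenerate("classification metrics need both classes present")
  pred <- scores >= threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(scores))
}
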