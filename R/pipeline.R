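# End-to-end pipeline: (simulate ->) score -> dichotomize -> learn ->
# sensitivity sweep -> cross-validate, with a run manifest for
# reproducibility. One global seed is split deterministically into
# per-stage seeds so a single integer reproduces a whole run.

#' Pipeline configuration
#'
#' @param items_path CSV of item-level survey responses (the
#'   [score_survey()] schema); `NULL` to simulate a cohort instead.
#' @param structure Network structure to learn on: a [bn_network()] or a
#'   path to a network file.
#' @param simulate A [generator_config()] used when `items_path` is `NULL`.
#' @param learn A [learn_settings()].
#' @param target,k,threshold Cross-validation target variable, fold count,
#'   and classification threshold.
#' @param safety_direction Dichotomization direction option, see
#'   [dichotomization_rules()].
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(items_path = NULL,
                            structure = bn_network(study_variables(), study_arcs()),
                            simulate = generator_config(),
                            learn = learn_settings(),
                            target = "participation", k = 10, threshold = 0.5,
                            safety_direction = "self_consistent",
                            seed = 1) {
  if (is.character(structure)) structure <- read_network(structure)
  if (!inherits(structure, "bn_network"))
    stop_validation("structure must be a bn_network or a network file path")
  if (!is.null(items_path) && !file.exists(items_path))
    stop_validation(sprintf("items file '%s' does not exist", items_path))
  structure(list(items_path = items_path, structure = structure,
                 simulate = simulate, learn = learn, target = target,
                 k = as.integer(k), threshold = threshold,
                 safety_direction = safety_direction, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (reading the item CSV, or
#' simulating one), instrument scoring and reliability, median
#' dichotomization, CPT learning (crosstab MLE on complete records, EM when
#' cells are missing), the full sensitivity sweep, arc strength-of-influence,
#' and k-fold cross-validation with ROC analysis. All result tables plus a
#' run manifest (`manifest.json`: version, settings, seeds, input digests,
#' output list) are written under `out_dir`. Outputs are byte-identical
#' across reruns with the same inputs and seed. Any stage failure aborts
#' with the stage named in the error.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    outputs <<- c(outputs, name)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      bn_stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
              class(e)[1])
    })
  }

  # --- acquire ---------------------------------------------------------
  cohort <- NULL
  items <- stage("acquire", {
    if (is.null(config$items_path)) {
      sim_cfg <- config$simulate
      sim_cfg$seed <- derive_seed(config$seed, 11L)
      cohort <- simulate_cohort(sim_cfg)   # assigns in run_pipeline's frame
      emit("items.csv", function(p) write_records(cohort$items, p))
      emit("states_truth.csv", function(p) write_records(cohort$states, p))
      emit("network_generator.json", function(p) write_network(cohort$model, p))
      cohort$items
    } else {
      read_records(config$items_path)
    }
  })

  # --- score + dichotomize --------------------------------------------
  scored <- stage("score", {
    scores <- score_survey(items)
    medians <- compute_medians(scores[setdiff(names(scores), "id")])
    rules <- dichotomization_rules(medians, config$safety_direction)
    states <- dichotomize(scores, rules)
    alpha <- c(
      mbi = cronbach_alpha(items[grep("^mbi_", names(items))]),
      cdrisc = cronbach_alpha(items[grep("^cd_", names(items))]),
      safety = cronbach_alpha(items[grep("^sb_", names(items))]))
    out <- cbind(scores, states[setdiff(names(states), "id")])
    emit("scored.csv", function(p) write_records(out, p))
    emit("reliability.json", function(p)
      jsonlite::write_json(list(cronbach_alpha = as.list(alpha),
                                medians = as.list(medians)),
                           p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
    list(states = states, medians = medians)
  })

  # EM test input: when simulating with missingness, learn on the blanked
  # ground-truth states; otherwise on the dichotomized survey states
  records <- if (!is.null(cohort) && config$simulate$missing_rate > 0) {
    cohort$states_observed
  } else scored$states
  records <- records[setdiff(names(records), "id")]

  # --- learn -----------------------------------------------------------
  learned <- stage("learn", {
    if (anyNA(records)) {
      fit <- em_learn(records, config$structure, config$learn)
      emit("em_log.csv", function(p)
        utils::write.csv(fit$log, p, row.names = FALSE))
      fit$network
    } else {
      mle_cpts(records, config$structure, config$learn$pseudocount)
    }
  })
  emit("network_learned.json", function(p) write_network(learned, p))

  # --- sensitivity -----------------------------------------------------
  sweep <- stage("sensitivity", full_sensitivity_sweep(learned))
  emit("sensitivity_univariate.csv", function(p)
    utils::write.csv(sweep$univariate_table, p, row.names = FALSE))
  emit("sensitivity_multivariate.csv", function(p)
    utils::write.csv(sweep$multivariate_table, p, row.names = FALSE))
  soi <- stage("sensitivity", strength_of_influence_table(learned))
  emit("strength_of_influence.csv", function(p)
    utils::write.csv(soi, p, row.names = FALSE))

  # --- validate --------------------------------------------------------
  metrics <- stage("validate", {
    records <- records[!is.na(records[[config$target]]), , drop = FALSE]
    preds <- cross_validate(records, config$structure, config$target,
                            config$learn, k = config$k,
                            seed = derive_seed(config$seed, 23L))
    emit("cv_predictions.csv", function(p)
      utils::write.csv(as.data.frame(preds), p, row.names = FALSE))
    roc <- roc_curve(preds)
    cm <- classification_metrics(preds, threshold = config$threshold)
    list(target = config$target, auc = roc$auc,
         youden_threshold = roc$youden, threshold = config$threshold,
         sensitivity = unname(cm["sensitivity"]),
         specificity = unname(cm["specificity"]),
         accuracy = unname(cm["accuracy"]))
  })
  emit("validation_metrics.json", function(p)
    jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))

  manifest <- list(
    tool = "burnoutbn",
    version = as.character(utils::packageVersion("burnoutbn")),
    seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, 11L),
                       folds = derive_seed(config$seed, 23L)),
    settings = list(target = config$target, k = config$k,
                    threshold = config$threshold,
                    safety_direction = config$safety_direction,
                    em_tolerance = config$learn$tolerance,
                    em_max_iterations = config$learn$max_iterations,
                    pseudocount = config$learn$pseudocount),
    inputs = if (is.null(config$items_path)) list() else
      list(items = list(path = config$items_path,
                        md5 = unname(tools::md5sum(config$items_path)))),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
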