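#' Define a survey instrument
#'
#' An instrument is a fixed-length battery of Likert-type items partitioned
#' into subscales. Each subscale score is the plain sum of its item scores;
#' no individual items are reverse-scored (score direction is handled later,
#' at dichotomization).
#'
#' @param name Instrument name, e.g. `"MBI"`.
#' @param item_count Number of items in the battery.
#' @param item_range Length-2 integer vector, the inclusive per-item score
#'   range (MBI 0-6, CD-RISC 0-4, safety behavior 1-5).
#' @param subscales Named list mapping subscale name to the 1-based item
#'   indices it owns. Subscales must be disjoint and together cover every
#'   item exactly once.
#' @return An object of class `instrument_spec`.
#' @seealso [mbi_spec()], [cdrisc_spec()], [safety_spec()]
#' @export
instrument_spec <- function(name, item_count, item_range, subscales) {
  if (!is.character(name) || length(name) != 1L)
    stop_validation("instrument name must be a single string")
  if (!is_whole(item_count) || length(item_count) != 1L || item_count < 1)
    stop_validation("item_count must be a positive integer")
  if (length(item_range) != 2L || !is_whole(item_range) || item_range[1] > item_range[2])
    stop_validation("item_range must be an increasing length-2 integer vector")
  if (!is.list(subscales) || is.null(names(subscales)) || any(names(subscales) == ""))
    stop_validation("subscales must be a named list of item index vectors")
  idx <- unlist(subscales, use.names = FALSE)
  if (anyDuplicated(idx))
    stop_validation(sprintf("instrument '%s': subscales share items (%s)",
                            name, paste(idx[duplicated(idx)], collapse = ", ")))
  if (!setequal(idx, seq_len(item_count)))
    stop_validation(sprintf(
      "instrument '%s': subscale items must cover exactly 1..%d", name, item_count))
  structure(
    list(name = name, item_count = as.integer(item_count),
         item_range = as.integer(item_range),
         subscales = lapply(subscales, as.integer)),
    class = "instrument_spec")
}

#' Maslach Burnout Inventory specification
#'
#' 22 items on a 0-6 frequency scale with three subscales: emotional
#' exhaustion (EE, 9 items), depersonalization (DP, 5 items), and personal
#' accomplishment (PA_raw, 8 items). The default item-to-subscale mapping is
#' the standard MBI-HSS assignment; pass a different `subscales` list to
#' override it.
#'
#' @param subscales Optional replacement subscale mapping.
#' @return An `instrument_spec`.
#' @export
mbi_spec <- function(subscales = NULL) {
  default <- list(
    EE     = c(1, 2, 3, 6, 8, 13, 14, 16, 20),
    DP     = c(5, 10, 11, 15, 22),
    PA_raw = c(4, 7, 9, 12, 17, 18, 19, 21))
  instrument_spec("MBI", 22, c(0, 6), subscales %||% default)
}

#' Connor-Davidson Resilience Scale specification
#'
#' 25 items on a 0-4 scale across five dimensions (personal competence 8,
#' tolerance of negative affect 5, acceptance of change 7, control 3,
#' spiritual influence 2). The resilience total used for modelling is the sum
#' of all dimension scores.
#'
#' @param subscales Optional replacement subscale mapping.
#' @return An `instrument_spec`.
#' @export
cdrisc_spec <- function(subscales = NULL) {
  default <- list(
    competence = 1:8,
    tolerance  = 9:13,
    acceptance = 14:20,
    control    = 21:23,
    spiritual  = 24:25)
  instrument_spec("CD-RISC", 25, c(0, 4), subscales %||% default)
}

#' Safety behavior assessment specification
#'
#' 23 items on a 1-5 agreement scale: safety compliance (12 items) and safety
#' participation (11 items). Higher raw scores indicate better safety
#' behavior; the model variables are the "poor" variants, so direction is
#' flipped at dichotomization.
#'
#' @param subscales Optional replacement subscale mapping.
#' @return An `instrument_spec`.
#' @export
safety_spec <- function(subscales = NULL) {
  default <- list(compliance_raw = 1:12, participation_raw = 13:23)
  instrument_spec("safety", 23, c(1, 5), subscales %||% default)
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("<instrument_spec> %s: %d items in [%d, %d]\n",
              x$name, x$item_count, x$item_range[1], x$item_range[2]))
  for (s in names(x$subscales))
    cat(sprintf("  %s: %d items\n", s, length(x$subscales[[s]])))
  invisible(x)
}

#' Default instrument set for the six-variable model
#'
#' @return Named list with elements `mbi`, `cdrisc`, `safety`.
#' @export
default_instrument_specs <- function() {
  list(mbi = mbi_spec(), cdrisc = cdrisc_spec(), safety = safety_spec())
}

#' Score an instrument from item-level responses
#'
#' Computes one subscale score per subscale as the sum of that subscale's
#' item scores.
#'
#' @param responses A numeric vector of length `spec$item_count` (one
#'   respondent), or a matrix/data.frame with one row per respondent and
#'   `spec$item_count` columns.
#' @param spec An [instrument_spec()].
#' @param ids Optional respondent identifiers used in error messages and as
#'   row names of the result.
#' @param allow_na If `TRUE`, missing items are tolerated and any subscale
#'   containing a missing item scores `NA`; if `FALSE` (default) a missing
#'   item is a validation error.
#' @return A data.frame with one row per respondent and one column per
#'   subscale.
#' @export
score_instrument <- function(responses, spec, ids = NULL, allow_na = FALSE) {
  stopifnot(inherits(spec, "instrument_spec"))
  if (is.null(dim(responses)))
    responses <- matrix(as.numeric(responses), nrow = 1)
  responses <- as.matrix(responses)
  storage.mode(responses) <- "double"
  if (ncol(responses) != spec$item_count)
    stop_validation(sprintf(
      "instrument '%s' expects %d items per respondent, got %d",
      spec$name, spec$item_count, ncol(responses)))
  ids <- ids %||% seq_len(nrow(responses))
  bad_na <- which(is.na(responses), arr.ind = TRUE)
  if (nrow(bad_na) > 0 && !allow_na) {
    b <- bad_na[1, ]
    stop_validation(sprintf(
      "instrument '%s': respondent %s item %d is missing (set allow_na = TRUE to score around it)",
      spec$name, ids[b[1]], b[2]))
  }
  out_of_range <- which(!is.na(responses) &
                          (responses < spec$item_range[1] |
                             responses > spec$item_range[2]),
                        arr.ind = TRUE)
  if (nrow(out_of_range) > 0) {
    b <- out_of_range[1, ]
    stop_validation(sprintf(
      "instrument '%s': respondent %s item %d has value %s outside [%d, %d]",
      spec$name, ids[b[1]], b[2], format(responses[b[1], b[2]]),
      spec$item_range[1], spec$item_range[2]))
  }
  scores <- vapply(spec$subscales, function(ix) rowSums(responses[, ix, drop = FALSE]),
                   numeric(nrow(responses)))
  if (nrow(responses) == 1L) scores <- matrix(scores, nrow = 1, dimnames = list(NULL, names(spec$subscales)))
  out <- as.data.frame(scores)
  rownames(out) <- ids
  out
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`, with
#' sample (n-1) variances. Alpha is at most 1 and can be negative for items
#' that covary negatively.
#'
#' @param items Numeric matrix or data.frame, respondents in rows, items in
#'   columns; at least 2 items and 2 respondents.
#' @return The alpha coefficient (single number).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  storage.mode(items) <- "double"
  if (anyNA(items))
    stop_validation("cronbach_alpha requires complete item responses")
  k <- ncol(items)
  if (k < 2L || nrow(items) < 2L)
    stop_validation("cronbach_alpha needs at least 2 items and 2 respondents")
  total_var <- stats::var(rowSums(items))
  if (total_var <= 0)
    stop_degenerate("total-score variance is zero; alpha is undefined for constant totals")
  item_var <- sum(apply(items, 2, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Per-construct median thresholds
#'
#' The sample median of each construct's scores, used as the low/high cut
#' point. Even-n medians are the mean of the two middle order statistics.
#'
#' @param scores A data.frame (or named list) of numeric construct score
#'   vectors.
#' @return Named numeric vector of thresholds.
#' @export
compute_medians <- function(scores) {
  if (is.data.frame(scores)) scores <- as.list(scores)
  if (!is.list(scores) || is.null(names(scores)))
    stop_validation("scores must be a named list or data.frame of construct scores")
  vapply(names(scores), function(nm) {
    x <- scores[[nm]]
    x <- x[!is.na(x)]
    if (length(x) == 0)
      stop_validation(sprintf("construct '%s' has no scores to take a median of", nm))
    stats::median(x)
  }, numeric(1))
}

# construct -> model-variable map with score direction.
# high_when = "above": raw score above the median is the undesired state
# (EE, DP); "below": the undesired model state corresponds to a raw score
# below the median (reduced PA, poor resilience, poor compliance/participation).
construct_table <- function(safety_direction = c("self_consistent", "literal")) {
  safety_direction <- match.arg(safety_direction)
  tab <- data.frame(
    construct = c("EE", "DP", "PA_raw", "resilience_raw",
                  "compliance_raw", "participation_raw"),
    variable  = c("EE", "DP", "PA", "resilience", "compliance", "participation"),
    high_when = c("above", "above", "below", "below", "below", "below"),
    stringsAsFactors = FALSE)
  if (safety_direction == "literal") {
    # the alternative reading: poor safety state tied to scores above the median
    tab$high_when[tab$variable %in% c("compliance", "participation")] <- "above"
  }
  tab
}

#' Dichotomization rules from median thresholds
#'
#' Builds the rule set that turns the six raw construct scores into the six
#' binary model variables. "Low" is the desired state for every model
#' variable: high EE/DP means a raw score above the median, while high
#' (i.e. reduced) PA, poor resilience, poor compliance, and poor
#' participation mean a raw score below the median. Scores exactly at the
#' threshold always go to the desired "low" state.
#'
#' @param medians Named numeric vector of thresholds, names being the six
#'   raw construct names (`EE`, `DP`, `PA_raw`, `resilience_raw`,
#'   `compliance_raw`, `participation_raw`).
#' @param safety_direction `"self_consistent"` (default: poor safety behavior
#'   corresponds to raw safety scores below the median, consistent with
#'   higher scores meaning better behavior) or `"literal"` (poor safety
#'   behavior corresponds to scores above the median).
#' @return A data.frame of rules with columns `construct`, `variable`,
#'   `threshold`, `high_when`.
#' @export
dichotomization_rules <- function(medians,
                                  safety_direction = c("self_consistent", "literal")) {
  tab <- construct_table(safety_direction)
  missing <- setdiff(tab$construct, names(medians))
  if (length(missing) > 0)
    stop_validation(sprintf("no median threshold for construct(s): %s",
                            paste(missing, collapse = ", ")))
  tab$threshold <- as.numeric(medians[tab$construct])
  tab
}

#' Dichotomize construct scores into model-variable states
#'
#' Applies one [dichotomization_rules()] row per construct. For
#' `high_when = "above"` a score strictly above the threshold is "high"; for
#' `high_when = "below"` a score strictly below it is "high"; ties at the
#' threshold are always the desired "low" state. The mapping is idempotent
#' and fully determined by scores and rules.
#'
#' @param scores data.frame with the six raw construct columns (and
#'   optionally an `id` column, carried through).
#' @param rules Rule data.frame from [dichotomization_rules()].
#' @return data.frame with `id` plus one state column (`"low"`/`"high"`,
#'   `NA` for missing scores) per model variable.
#' @export
dichotomize <- function(scores, rules) {
  need <- c("construct", "variable", "threshold", "high_when")
  if (!is.data.frame(rules) || !all(need %in% names(rules)))
    stop_validation("rules must come from dichotomization_rules()")
  missing <- setdiff(rules$construct, names(scores))
  if (length(missing) > 0)
    stop_validation(sprintf("scores table lacks construct column(s): %s",
                            paste(missing, collapse = ", ")))
  if (anyDuplicated(rules$construct))
    stop_validation("duplicate dichotomization rule for a construct")
  n <- nrow(scores)
  out <- data.frame(id = scores$id %||% seq_len(n))
  for (i in seq_len(nrow(rules))) {
    x <- scores[[rules$construct[i]]]
    thr <- rules$threshold[i]
    high <- if (rules$high_when[i] == "above") x > thr else x < thr
    out[[rules$variable[i]]] <- ifelse(is.na(x), NA_character_,
                                       ifelse(high, "high", "low"))
  }
  out
}

#' Score a full survey table
#'
#' Takes an item-level table with columns `mbi_01..mbi_22`, `cd_01..cd_25`,
#' `sb_01..sb_23` (plus optional demographics) and returns the six raw
#' construct scores per respondent: EE, DP, PA_raw (MBI subscales),
#' resilience_raw (CD-RISC total), compliance_raw and participation_raw
#' (safety subscales).
#'
#' @param data data.frame of item responses; empty/NA cells are missing items.
#' @param specs Instrument list from [default_instrument_specs()].
#' @param allow_na Tolerate missing items (affected construct scores become
#'   `NA`)? Default `TRUE`, matching survey practice.
#' @return data.frame with `id` and the six construct score columns.
#' @export
score_survey <- function(data, specs = default_instrument_specs(), allow_na = TRUE) {
  item_cols <- function(prefix, k) sprintf("%s_%02d", prefix, seq_len(k))
  for (cols in list(item_cols("mbi", 22), item_cols("cd", 25), item_cols("sb", 23))) {
    miss <- setdiff(cols, names(data))
    if (length(miss) > 0)
      stop_validation(sprintf("survey table lacks item column(s): %s",
                              paste(utils::head(miss, 5), collapse = ", ")))
  }
  ids <- data$id %||% seq_len(nrow(data))
  mbi <- score_instrument(data[item_cols("mbi", 22)], specs$mbi, ids, allow_na)
  cd  <- score_instrument(data[item_cols("cd", 25)],  specs$cdrisc, ids, allow_na)
  sb  <- score_instrument(data[item_cols("sb", 23)],  specs$safety, ids, allow_na)
  data.frame(id = ids,
             EE = mbi$EE, DP = mbi$DP, PA_raw = mbi$PA_raw,
             resilience_raw = rowSums(cd),
             compliance_raw = sb$compliance_raw,
             participation_raw = sb$participation_raw)
}
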