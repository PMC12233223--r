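# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
bn_stop <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "burnoutbn_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

stop_validation <- function(msg) bn_stop(msg, "validation_error")
stop_degenerate <- function(msg) bn_stop(msg, "degenerate_input_error")
stop_inconsistent_evidence <- function(msg) bn_stop(msg, "inconsistent_evidence_error")
stop_parse <- function(msg) bn_stop(msg, "parse_error")

# round half away from zero, as report tables print integer percentage points
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

is_whole <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < 1e-8)
}

# deterministic per-stage seed derivation from one pipeline seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}
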