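# Internal helpers shared across modules.

# Deterministic per-artifact sub-seed derived from one master seed.
# Keeps every derived seed a positive 32-bit integer.
substream_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(as.double(seed)) * 48271 + 7919 * offset) %% 2147483646
  as.integer(s) + 1L
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", field, min),
          class = "promrank_config_error")
  }
  as.integer(x)
}

check_number <- function(x, field, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number%s", field,
                  if (is.finite(min)) sprintf(" >= %g", min) else ""),
          class = "promrank_config_error")
  }
  as.double(x)
}

check_range <- function(x, field) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) ||
      x[1] > x[2] || any(x < 0)) {
    abort(sprintf("`%s` must be a non-negative length-2 vector c(lo, hi)", field),
          class = "promrank_config_error")
  }
  as.double(x)
}

# run `expr`, labelling any error with the pipeline stage that raised it
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "promrank_stage_error")
  })
}
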