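#' @keywords internal
"_PACKAGE"

# Classed conditions so callers/tests can distinguish bad configuration
# from bad data without string-matching messages.
abort_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("stepsig_config_error", "error")))
}

abort_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("stepsig_input_error", "error")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage sub-seed derived from the master seed, so each
# stage (counts, lengths, covariates, survival) draws from its own stream
# and can be regenerated independently. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(counts = 1L, lengths = 2L, covariates = 3L, survival = 4L,
               bimodal = 5L)
  if (!stage %in% names(offsets)) abort_config("unknown RNG stage: ", stage)
  (as.integer(seed) %% 1000000L) * 2048L + offsets[[stage]]
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper &&
    (!integer || x == round(x))
  if (!ok) {
    abort_config("invalid value for '", name, "': must be a ",
                 if (integer) "whole number" else "finite number",
                 if (is.finite(lower)) paste0(" ", if (strict_lower) "> " else ">= ", lower) else "",
                 if (is.finite(upper)) paste0(" and <= ", upper) else "",
                 " (got ", deparse(x), ")")
  }
  invisible(x)
}
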