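#' Derive a stage-specific seed from a root seed
#'
#' All randomness in the package flows from one root seed; each stage (and
#' each subject, case, ...) uses a seed derived deterministically from it so
#' that stages can be rerun in isolation without disturbing one another.
#'
#' @param seed integer root seed.
#' @param stage character stage label.
#' @param index optional integer sub-index (subject number, case number, ...).
#' @return an integer seed in [0, 2^31 - 1).
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, keeps derived seeds valid 32-bit integers
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% m
  as.integer((abs(seed) %% m * 48271 + h * 16807 + abs(index) %% m * 69621) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
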