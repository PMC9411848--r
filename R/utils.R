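#' @keywords internal
"_PACKAGE"

# Validation / error helpers ------------------------------------------------

abort_validation <- function(msg, ...) {
  stop(structure(class = c("pdscreen_validation_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

abort_io <- function(msg, ...) {
  stop(structure(class = c("pdscreen_io_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) abort_validation(msg, ...)
  invisible(TRUE)
}

# Seed plumbing --------------------------------------------------------------
# Stochastic entry points take `seed = NULL`: a given seed makes the call
# reproducible without disturbing the caller's RNG stream; NULL uses the
# ambient stream.

with_seed_or_stream <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), force(code))
}

# Stable per-item seed fan-out so subsets of a fixture set regenerate
# identically. Knuth multiplicative hash, kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 2654435761 + as.numeric(index) * 97 + 13) %% 2147483587L)
}

log_stage <- function(stage, ...) {
  message(sprintf("[pdscreen:%s] %s", stage, sprintf(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
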