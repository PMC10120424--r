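# Internal helpers shared across modules.

# Deterministic child-seed derivation (Lehmer-style multiplicative hash).
# Every product stays below 2^53, so the arithmetic is exact in doubles and
# the derived stream for purpose/index i is unaffected by how many other
# streams exist (e.g. changing n_partitions never perturbs earlier partitions).
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1
  s <- ((abs(master) %% m) * 48271) %% m
  s <- ((s + index + 1) * 16807) %% m
  as.integer(s)
}

#' Half-up rounding
#'
#' Rounds halves away from zero, matching how reported percentages are
#' conventionally printed (base `round()` is half-to-even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
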