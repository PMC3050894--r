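#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-replicate seed from a master seed
#'
#' Bootstrap replicates and simulation batches each use an independent RNG
#' stream keyed by (seed, index) so results do not depend on execution order.
#' The derived value always fits a 32-bit signed integer.
#'
#' @param seed master seed (integer)
#' @param index replicate index (integer >= 0)
#' @return an integer seed
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  # Knuth-style multiplicative mix, kept in double precision below 2^53
  # and folded into [0, 2^31 - 2]
  h <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 16807 + 1
  as.integer(h %% 2147483646L) + 1L
}

#' @noRd
stop_altexon <- function(...) stop(..., call. = FALSE)

#' @noRd
is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
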