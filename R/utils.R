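`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Apportion a total into integer counts proportional to weights
#'
#' Largest-remainder (Hamilton) apportionment: counts sum exactly to `n` and
#' each count differs from `n * w / sum(w)` by less than 1.
#'
#' @param n total to distribute (non-negative integer).
#' @param weights non-negative numeric weights.
#' @return integer vector of counts, same length and names as `weights`.
#' @export
apportion <- function(n, weights) {
  stopifnot(n >= 0, all(weights >= 0), sum(weights) > 0)
  ideal <- n * weights / sum(weights)
  base <- floor(ideal)
  rem <- n - sum(base)
  if (rem > 0) {
    # ties in fractional part broken by position for determinism
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  counts <- as.integer(base)
  names(counts) <- names(weights)
  counts
}

# deterministic per-purpose sub-seed derived from a master seed; kept < 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629L)
}
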