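# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# z-score a numeric vector; constant vectors are an error unless allow_constant
zscore <- function(x, allow_constant = FALSE) {
  s <- stats::sd(x)
  if (s == 0) {
    if (allow_constant) return(rep(0, length(x)))
    stop("cannot standardize a constant vector", call. = FALSE)
  }
  (x - mean(x)) / s
}

# deterministic child seeds derived from one user seed (kept below 2^31);
# double arithmetic avoids integer overflow for seeds near the cap
derive_seed <- function(seed, offset) {
  (as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483647
}

# adjusted Rand index between two label vectors (used for planted-module recovery)
#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, 0 the expectation under independence.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  assert_that(length(a) == length(b), "label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxindex <- (sum_a + sum_b) / 2
  if (maxindex == expected) return(1)
  (sum_ij - expected) / (maxindex - expected)
}
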