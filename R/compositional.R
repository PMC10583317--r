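#' Count-zero multiplicative zero replacement
#'
#' Replaces zeros in each sample (column) by a small positive part and
#' multiplicatively shrinks the nonzero parts so the sample total is
#' preserved: zeros become `delta`, nonzero parts are multiplied by
#' `(1 - z * delta / T)` where `z` is the sample's zero count and `T` its
#' total. By default `delta` is 65% of the sample's smallest observed
#' nonzero part (multiplicative simple replacement); when a sample is so
#' sparse that the imputed mass `z * delta` would reach `delta_frac * T`,
#' `delta` is lowered to `delta_frac * T / z` so the adjusted observed
#' parts remain strictly positive.
#'
#' @param table an [abundance_table()] or nonnegative matrix.
#' @param delta_frac fraction of the per-sample minimum nonzero part used as
#'   the imputed value (default 0.65).
#' @return A strictly positive matrix of the same shape, totals preserved.
#' @export
czm_replace <- function(table, delta_frac = 0.65) {
  x <- unclass(as.matrix(table))
  assert_that(all(x >= 0), "abundances must be nonnegative")
  zero_sample <- colSums(x > 0) == 0
  assert_that(!any(zero_sample),
              sprintf("sample(s) entirely zero: %s",
                      paste(colnames(x)[zero_sample], collapse = ", ")))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    z <- sum(col == 0)
    if (z == 0) next
    total <- sum(col)
    delta <- delta_frac * min(col[col > 0])
    # keep the imputed mass a strict minority of the sample total so the
    # multiplicative adjustment of the observed parts stays positive
    if (z * delta >= delta_frac * total) delta <- delta_frac * total / z
    out[col == 0, j] <- delta
    out[col > 0, j] <- col[col > 0] * (1 - z * delta / total)
  }
  out
}

#' Centered log-ratio transform
#'
#' Per sample (column), `clr(x_f) = ln(x_f) - mean_f ln(x_f)`. Requires a
#' strictly positive matrix; run [czm_replace()] first when zeros are
#' present. Column sums of the result are 0 by construction, and the
#' transform is invariant to per-sample rescaling of the composition.
#'
#' @param positive_table strictly positive matrix, features x samples.
#' @return Matrix of log-ratios with the same dimnames.
#' @export
clr_transform <- function(positive_table) {
  x <- unclass(as.matrix(positive_table))
  assert_that(all(x > 0),
              "clr requires strictly positive entries; apply czm_replace first")
  lx <- log(x)
  sweep(lx, 2, colMeans(lx), "-")
}
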