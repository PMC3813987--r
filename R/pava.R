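#' Pooled adjacent violators algorithm (weighted isotonic regression)
#'
#' Computes the nondecreasing vector minimizing
#' \eqn{\sum_i w_i (out_i - values_i)^2}: whenever two adjacent blocks
#' violate monotonicity they are pooled and replaced by their weighted
#' mean, until no violation remains. Used by the isotonic designs to
#' estimate the per-dose mean toxicity under the monotone dose-toxicity
#' assumption.
#'
#' @param values numeric vector to be made nondecreasing.
#' @param weights positive weights (typically per-dose patient counts).
#' @return Numeric vector of the same length, nondecreasing, preserving the
#'   weighted mean over every pooled block.
#' @examples
#' pava(c(0.3, 0.1))            # pooled to (0.2, 0.2)
#' pava(c(0.1, 0.2, 0.15), c(3, 3, 6))
#' @export
pava <- function(values, weights = rep(1, length(values))) {
  m <- length(values)
  stopifnot(m >= 1L, length(weights) == m)
  if (any(!is.finite(values)) || any(!is.finite(weights)))
    stop("'values' and 'weights' must be finite")
  if (any(weights <= 0)) stop("weights must be strictly positive")
  # stack of blocks: fitted value, weight, and number of members
  val <- numeric(m); wt <- numeric(m); len <- integer(m)
  top <- 0L
  for (i in seq_len(m)) {
    top <- top + 1L
    val[top] <- values[i]; wt[top] <- weights[i]; len[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      w <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) / w
      wt[top - 1L] <- w
      len[top - 1L] <- len[top - 1L] + len[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], len[seq_len(top)])
}
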