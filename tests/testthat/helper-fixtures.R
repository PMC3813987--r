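# Shared fixtures for the test suite. Everything is built in code.

ex_basis <- example_weight_matrix()
ex_w <- ex_basis$weights
ex_nu <- ex_basis$nu
ex_theta <- ex_basis$theta_star

# The two worked elicitation cohorts (grades: renal, neurological,
# hematological per patient).
worked_cohort_1 <- rbind(c(2, 2, 2), c(1, 1, 3), c(0, 0, 0))
worked_cohort_2 <- rbind(c(3, 0, 0), c(0, 2, 1), c(1, 0, 2))

# A random valid scenario: Dirichlet-ish rows (normalized exponentials).
random_scenario <- function(K = 6L, L = 3L, true_rd = NULL) {
  P <- lapply(seq_len(L), function(l) {
    m <- matrix(stats::rexp(K * 5), K, 5)
    m / rowSums(m)
  })
  names(P) <- paste0("tox", seq_len(L))
  scenario(P, true_rd = true_rd)
}

# A scenario putting all mass on a fixed grade vector at every dose.
degenerate_scenario <- function(grades, K = 6L, true_rd = NULL) {
  P <- lapply(grades, function(g) {
    m <- matrix(0, K, 5)
    m[, g + 1L] <- 1
    m
  })
  names(P) <- paste0("tox", seq_along(grades))
  scenario(P, true_rd = true_rd)
}

# Brute-force weighted isotonic least squares: minimize sum w (f - v)^2 over
# all nondecreasing block partitions (fitted value constant per block, equal
# to the block's weighted mean). Exact for m <= ~10.
brute_force_isotonic <- function(values, weights = rep(1, length(values))) {
  m <- length(values)
  if (m == 1L) return(values)
  best <- NULL; best_sse <- Inf
  # each of the 2^(m-1) cut patterns defines consecutive blocks
  for (mask in 0:(2^(m - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(m - 2))) > 0)
    starts <- c(1L, cuts + 1L); ends <- c(cuts, m)
    fit <- numeric(m)
    means <- numeric(length(starts))
    for (bk in seq_along(starts)) {
      idx <- starts[bk]:ends[bk]
      means[bk] <- sum(weights[idx] * values[idx]) / sum(weights[idx])
      fit[idx] <- means[bk]
    }
    if (is.unsorted(means)) next
    sse <- sum(weights * (fit - values)^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- fit }
  }
  best
}
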