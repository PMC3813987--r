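#' Dose-toxicity scenario from per-toxicity grade-probability matrices
#'
#' A scenario specifies, for each of L independent toxicity types, a K x 5
#' matrix of probabilities of observing grades 0..4 at each of K dose
#' levels. Together with a weight matrix it determines the full distribution
#' of the nTTP score at every dose, computable exactly by enumerating the
#' \eqn{5^L} toxicity profiles.
#'
#' @param probs a list of L numeric K x 5 matrices (rows = dose levels,
#'   columns = grades 0..4), each row summing to 1; or a single matrix for
#'   L = 1. Names of the list are taken as toxicity names.
#' @param true_rd optional integer: the dose level regarded as the true
#'   recommended dose (RD) of the scenario, used to score correct selection
#'   in simulations.
#' @return An object of class \code{"nttp_scenario"}: a list with elements
#'   \code{P} (list of matrices), \code{K}, \code{L}, \code{true_rd}.
#' @seealso [scenario_moments()], [sample_patient()], [calibrate_scenario()]
#' @export
scenario <- function(probs, true_rd = NULL) {
  if (is.matrix(probs)) probs <- list(probs)
  stopifnot(is.list(probs), length(probs) >= 1L)
  probs <- lapply(probs, as.matrix)
  K <- nrow(probs[[1L]])
  for (m in probs) {
    if (ncol(m) != 5L) stop("each probability matrix needs 5 columns (grades 0..4)")
    if (nrow(m) != K) stop("all probability matrices must share the number of dose levels")
    if (any(!is.finite(m)) || any(m < -1e-15)) stop("probabilities must be nonnegative")
    if (any(abs(rowSums(m) - 1) > 1e-12))
      stop("each dose-level row must sum to 1 (tolerance 1e-12)")
  }
  if (is.null(names(probs))) names(probs) <- paste0("tox", seq_along(probs))
  if (!is.null(true_rd)) {
    true_rd <- as.integer(true_rd)
    stopifnot(length(true_rd) == 1L, true_rd >= 1L, true_rd <= K)
  }
  structure(list(P = probs, K = K, L = length(probs), true_rd = true_rd),
            class = "nttp_scenario")
}

#' @export
print.nttp_scenario <- function(x, ...) {
  cat("Dose-toxicity scenario:", x$L, "toxicity types,", x$K, "dose levels\n")
  if (!is.null(x$true_rd)) cat("True RD: dose", x$true_rd, "\n")
  invisible(x)
}

# All 5^L grade vectors, toxicity 1 varying fastest (matches the outer-product
# ordering used in profile_distribution).
profile_grid <- function(L) {
  as.matrix(do.call(expand.grid, rep(list(0:4), L)))
}

check_enumeration_guard <- function(L) {
  if (L > 4L)
    stop("exact enumeration is limited to at most 4 toxicity types (5^L profiles); ",
         "use Monte Carlo moments for larger L")
}

#' Exact distribution over toxicity profiles at one dose
#'
#' Under independence of the toxicity types, the probability of the grade
#' vector \eqn{(j_1, \dots, j_L)} at dose \eqn{d_k} is the product of the
#' per-toxicity grade probabilities. Profiles are ordered as in
#' \code{expand.grid(0:4, ...)}: the first toxicity's grade varies fastest.
#'
#' @param s an [scenario()].
#' @param dose_index dose level in \code{1..K}.
#' @return Numeric vector of \eqn{5^L} probabilities summing to 1, with the
#'   corresponding grade matrix attached as attribute \code{"profiles"}.
#' @export
profile_distribution <- function(s, dose_index) {
  stopifnot(inherits(s, "nttp_scenario"))
  check_enumeration_guard(s$L)
  k <- as.integer(dose_index)
  if (length(k) != 1L || k < 1L || k > s$K)
    stop("'dose_index' must be a single dose level in 1..", s$K)
  p <- s$P[[1L]][k, ]
  if (s$L > 1L) for (l in 2:s$L) p <- as.vector(outer(p, s$P[[l]][k, ]))
  structure(unname(p), profiles = profile_grid(s$L))
}

#' Exact per-dose mean nTTP and DLT probability of a scenario
#'
#' Enumerates the \eqn{5^L} toxicity profiles at each dose level and returns
#' the probability-weighted mean nTTP and the probability of observing a
#' DLT, the two quantities that summarize a scenario's toxicity burden.
#'
#' @inheritParams profile_distribution
#' @inheritParams nttp
#' @return A data frame with one row per dose: \code{dose},
#'   \code{mean_nttp}, \code{p_dlt}.
#' @export
scenario_moments <- function(s, w, nu) {
  stopifnot(inherits(s, "nttp_scenario"), inherits(w, "nttp_weights"))
  check_enumeration_guard(s$L)
  if (s$L != length(w$toxicities))
    stop("scenario has ", s$L, " toxicity types but the weight matrix has ",
         length(w$toxicities))
  grid <- profile_grid(s$L)
  y <- nttp(grid, w, nu)
  d <- is_dlt(grid, w)
  mean_nttp <- p_dlt <- numeric(s$K)
  for (k in seq_len(s$K)) {
    p <- profile_distribution(s, k)
    mean_nttp[k] <- sum(p * y)
    p_dlt[k] <- sum(p * d)
  }
  data.frame(dose = seq_len(s$K), mean_nttp = mean_nttp, p_dlt = p_dlt)
}

#' Sample patient toxicity profiles from a scenario
#'
#' Draws each toxicity grade independently from the scenario's
#' grade-probability row at the given dose, using R's current RNG stream
#' (seed it with [set.seed()] for reproducibility).
#'
#' @inheritParams profile_distribution
#' @param n number of patients to draw.
#' @return An \code{n x L} integer matrix of grades.
#' @export
sample_patient <- function(s, dose_index, n = 1L) {
  stopifnot(inherits(s, "nttp_scenario"))
  k <- as.integer(dose_index)
  if (length(k) != 1L || k < 1L || k > s$K)
    stop("'dose_index' must be a single dose level in 1..", s$K)
  g <- matrix(0L, n, s$L, dimnames = list(NULL, names(s$P)))
  for (l in seq_len(s$L))
    g[, l] <- sample.int(5L, n, replace = TRUE, prob = s$P[[l]][k, ]) - 1L
  g
}

# TRUE when v rises then falls (weak monotonicity allowed, single mode).
is_unimodal <- function(v) {
  d <- sign(diff(v))
  d <- d[d != 0]
  !is.unsorted(rev(d))
}

#' Check the unimodality structure of a scenario
#'
#' A plausible scenario has, for each toxicity type, a unimodal probability
#' of each grade across dose levels, with the grade-0 probability
#' nonincreasing in dose and the grade-4 probability nondecreasing in dose.
#' This diagnostic reports every (toxicity, grade) column violating those
#' shape constraints; an empty result means the scenario is well formed.
#'
#' @inheritParams profile_distribution
#' @return A data frame of violations with columns \code{toxicity},
#'   \code{grade}, \code{problem}; zero rows when none.
#' @export
validate_unimodal <- function(s) {
  stopifnot(inherits(s, "nttp_scenario"))
  out <- data.frame(toxicity = character(), grade = integer(),
                    problem = character(), stringsAsFactors = FALSE)
  for (l in seq_len(s$L)) {
    m <- s$P[[l]]
    for (j in 0:4) {
      v <- m[, j + 1L]
      if (j == 0L && is.unsorted(rev(v), strictly = FALSE) && any(diff(v) > 1e-12))
        out <- rbind(out, data.frame(toxicity = names(s$P)[l], grade = j,
                                     problem = "grade-0 probability increases with dose"))
      else if (j == 4L && is.unsorted(v) && any(diff(v) < -1e-12))
        out <- rbind(out, data.frame(toxicity = names(s$P)[l], grade = j,
                                     problem = "grade-4 probability decreases with dose"))
      else if (j %in% 1:3 && !is_unimodal(v))
        out <- rbind(out, data.frame(toxicity = names(s$P)[l], grade = j,
                                     problem = "grade probability not unimodal across doses"))
    }
  }
  out
}

# Grade probabilities from a latent-logistic (proportional-odds) severity s:
# P(grade >= j) = plogis(s - cut[j]).
grade_probs_from_severity <- function(sev, cutpoints) {
  cdf <- stats::plogis(sev - cutpoints)      # P(grade >= 1..4)
  c(1 - cdf[1L], -diff(cdf), cdf[4L])
}

#' Calibrate a scenario to target mean-nTTP values
#'
#' Builds a valid scenario whose exact per-dose mean nTTP matches a target
#' vector. Each dose level gets one latent severity parameter, shared by all
#' toxicity types, that generates the five grade probabilities through a
#' proportional-odds model with fixed cutpoints; mean nTTP is continuous and
#' strictly increasing in the severity, so each target is solved by
#' one-dimensional root finding. Because the grade distributions of a
#' proportional-odds family are unimodal in the latent scale, a scenario
#' calibrated to an increasing target vector automatically satisfies the
#' unimodality shape constraints checked by [validate_unimodal()].
#'
#' Only the mean-nTTP vector is matched (one degree of freedom per dose);
#' the implied DLT probabilities are whatever the latent model produces and
#' are returned for inspection.
#'
#' @param mean_nttp numeric vector of K target mean-nTTP values in (0, 1).
#' @inheritParams nttp
#' @param cutpoints increasing numeric vector of 4 latent thresholds between
#'   successive grades; the default gives realistically skewed grade
#'   distributions at low doses.
#' @param true_rd optional true RD index attached to the result; defaults to
#'   the dose whose target is closest to none (left unset).
#' @param tol absolute tolerance on the achieved mean nTTP (default 0.01;
#'   root finding typically achieves far better).
#' @return An [scenario()] with attribute \code{"calibration"}: a data frame
#'   of the targets, achieved moments, and residuals.
#' @export
calibrate_scenario <- function(mean_nttp, w, nu, cutpoints = c(1.4, 3.2, 5.0, 6.8),
                               true_rd = NULL, tol = 0.01) {
  stopifnot(inherits(w, "nttp_weights"), length(cutpoints) == 4L,
            !is.unsorted(cutpoints, strictly = TRUE))
  L <- length(w$toxicities)
  check_enumeration_guard(L)
  if (any(mean_nttp <= 0 | mean_nttp >= 1))
    stop("targets must lie strictly in (0, 1)")
  grid <- profile_grid(L)
  y <- nttp(grid, w, nu)
  mean_at <- function(sev) {
    p <- grade_probs_from_severity(sev, cutpoints)
    pp <- p
    if (L > 1L) for (l in 2:L) pp <- as.vector(outer(pp, p))
    sum(pp * y)
  }
  lo <- -25; hi <- 25
  reachable <- c(mean_at(lo), mean_at(hi))
  K <- length(mean_nttp)
  sev <- numeric(K)
  for (k in seq_len(K)) {
    if (mean_nttp[k] <= reachable[1L] || mean_nttp[k] >= reachable[2L]) {
      resid <- min(abs(mean_nttp[k] - reachable))
      stop(sprintf(
        "target mean nTTP %.4f at dose %d is outside the achievable range (%.4g, %.4g); best residual %.4g",
        mean_nttp[k], k, reachable[1L], reachable[2L], resid))
    }
    sev[k] <- stats::uniroot(function(s) mean_at(s) - mean_nttp[k],
                             c(lo, hi), tol = 1e-10)$root
  }
  P <- t(vapply(sev, grade_probs_from_severity, numeric(5), cutpoints = cutpoints))
  sc <- scenario(stats::setNames(rep(list(P), L), w$toxicities), true_rd = true_rd)
  mom <- scenario_moments(sc, w, nu)
  resid <- abs(mom$mean_nttp - mean_nttp)
  if (any(resid > tol))
    stop("calibration did not reach the requested tolerance; best residual ",
         format(max(resid), digits = 4))
  attr(sc, "calibration") <- data.frame(
    dose = seq_len(K), target = mean_nttp, achieved = mom$mean_nttp,
    residual = mom$mean_nttp - mean_nttp, p_dlt = mom$p_dlt, severity = sev)
  sc
}

#' Benchmark scenario targets
#'
#' Eight benchmark dose-toxicity patterns (labelled A-H) over six dose
#' levels, each given by its per-dose mean nTTP, implied DLT probability,
#' and true RD, spanning positions of the RD across the dose scale and mild
#' perturbations of the target value at the RD. The full per-toxicity
#' grade-probability matrices behind the original patterns are not publicly
#' available, so these rows serve as calibration targets for
#' [benchmark_scenario()], which reconstructs look-alike scenarios matching
#' the mean-nTTP rows; reconstructed scenarios are not claimed identical to
#' the originals (in particular their DLT probabilities differ).
#'
#' @return A data frame with columns \code{scenario}, \code{dose},
#'   \code{mean_nttp}, \code{p_dlt}, \code{true_rd}.
#' @export
benchmark_targets <- function() {
  rows <- list(
    A = list(nttp = c(0.183, 0.280, 0.359, 0.409, 0.432, 0.439),
             pdlt = c(0.195, 0.330, 0.447, 0.512, 0.557, 0.558), rd = 2L),
    B = list(nttp = c(0.100, 0.198, 0.310, 0.390, 0.441, 0.481),
             pdlt = c(0.057, 0.182, 0.379, 0.491, 0.592, 0.656), rd = 3L),
    C = list(nttp = c(0.108, 0.183, 0.280, 0.359, 0.409, 0.432),
             pdlt = c(0.065, 0.195, 0.330, 0.447, 0.512, 0.557), rd = 3L),
    D = list(nttp = c(0.051, 0.119, 0.270, 0.370, 0.404, 0.460),
             pdlt = c(0.002, 0.014, 0.169, 0.319, 0.417, 0.554), rd = 3L),
    E = list(nttp = c(0.051, 0.096, 0.188, 0.312, 0.418, 0.446),
             pdlt = c(0.002, 0.014, 0.186, 0.320, 0.506, 0.554), rd = 4L),
    F = list(nttp = c(0.054, 0.108, 0.183, 0.280, 0.359, 0.409),
             pdlt = c(0.011, 0.065, 0.195, 0.330, 0.447, 0.512), rd = 4L),
    G = list(nttp = c(0.045, 0.054, 0.108, 0.183, 0.280, 0.359),
             pdlt = c(0.008, 0.011, 0.065, 0.195, 0.330, 0.447), rd = 5L),
    H = list(nttp = c(0.051, 0.111, 0.141, 0.189, 0.253, 0.352),
             pdlt = c(0.001, 0.006, 0.015, 0.032, 0.097, 0.196), rd = 5L))
  do.call(rbind, lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    data.frame(scenario = nm, dose = 1:6, mean_nttp = r$nttp,
               p_dlt = r$pdlt, true_rd = r$rd)
  }))
}

#' Reconstruct a benchmark scenario by calibration
#'
#' Calibrates a scenario (see [calibrate_scenario()]) whose exact mean-nTTP
#' vector matches one of the [benchmark_targets()] rows, with the matching
#' true RD attached.
#'
#' @param name scenario label, one of \code{"A"} to \code{"H"}.
#' @inheritParams nttp
#' @param ... passed to [calibrate_scenario()].
#' @return A calibrated [scenario()].
#' @export
benchmark_scenario <- function(name, w = example_weight_matrix()$weights,
                               nu = 2.5, ...) {
  tg <- benchmark_targets()
  name <- match.arg(toupper(name), unique(tg$scenario))
  row <- tg[tg$scenario == name, ]
  calibrate_scenario(row$mean_nttp, w, nu, true_rd = row$true_rd[1L], ...)
}
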