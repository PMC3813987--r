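# Quasi-likelihood objectives for the slope of a one-parameter
# dose-toxicity model driven by the fractional nTTP response, and their
# frequentist / Bayesian summaries.

clamp01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Per-observation quasi-Bernoulli contribution: y log p + (1-y) log(1-p).
q_bernoulli <- function(y, p) {
  p <- clamp01(p)
  y * log(p) + (1 - y) * log1p(-p)
}

# Wedderburn quasi-likelihood Q(y, p) = int_y^p (y - t) / (t^2 (1-t)^2) dt,
# from the variance function V(p) = p^2 (1-p)^2. Closed form by partial
# fractions; antiderivative of the integrand in t:
#   F(y, t) = -y/t + y/(1-t) + (2y - 1) log(t/(1-t)) - 1/(1-t)
# Q(y, p) = F(y, p) - F(y, y), so Q(y, y) = 0 and Q <= 0 elsewhere.
wedderburn_F <- function(y, t) {
  -y / t + y / (1 - t) + (2 * y - 1) * log(t / (1 - t)) - 1 / (1 - t)
}

q_wedderburn <- function(y, p, y_clamp = 1e-6) {
  # Q diverges as y -> 0 or 1; boundary responses are pulled just inside.
  y <- pmin(pmax(y, y_clamp), 1 - y_clamp)
  p <- clamp01(p, 1e-9)
  wedderburn_F(y, p) - wedderburn_F(y, y)
}

check_obs <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(y) == 0L) stop("at least one observation is required")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("observations must be finite")
  if (any(y < 0 | y > 1)) stop("responses must lie in [0, 1]")
  invisible(NULL)
}

#' Quasi-Bernoulli log-likelihood of the slope
#'
#' Treats each normalized toxicity score \eqn{y_i \in [0, 1)} observed at
#' pseudo-dose \eqn{x_i} as a fractional Bernoulli event with mean
#' \eqn{p_i = \psi(x_i, b)} and returns
#' \deqn{\sum_i y_i \log p_i + (1 - y_i)\log(1 - p_i),}
#' the quasi-likelihood implied by the Bernoulli variance
#' \eqn{V(p) = p(1-p)}. With binary \eqn{y} it is exactly the classic CRM
#' log-likelihood.
#'
#' @param x pseudo-doses of the observations.
#' @param y nTTP responses in \eqn{[0, 1)}.
#' @param b slope at which to evaluate.
#' @param model an [model_spec()].
#' @return The objective value (a single number).
#' @export
quasi_loglik <- function(x, y, b, model) {
  check_obs(x, y)
  sum(q_bernoulli(y, psi(x, b, model)))
}

#' Wedderburn quasi-log-likelihood of the slope
#'
#' Alternative objective built from the Wedderburn variance function
#' \eqn{V(p) = p^2(1-p)^2}:
#' \deqn{\sum_i Q(y_i, p_i), \quad Q(y, p) = \int_y^p \frac{y - t}{t^2 (1 - t)^2}\,dt,}
#' evaluated in closed form (partial fractions). \eqn{Q(y, p)} is maximized
#' in \eqn{p} at \eqn{p = y}, the defining quasi-score property. The
#' integral diverges at boundary responses, so \eqn{y} is clamped to
#' \eqn{[10^{-6}, 1 - 10^{-6}]} before evaluation; this keeps all-grade-zero
#' patients usable under this variance choice.
#'
#' @inheritParams quasi_loglik
#' @return The objective value (a single number).
#' @export
wedderburn_quasi_loglik <- function(x, y, b, model) {
  check_obs(x, y)
  sum(q_wedderburn(y, psi(x, b, model)))
}

# Mean-toxicity matrix: rows = observations, columns = slope values.
psi_outer <- function(x, b, model) {
  switch(model$link,
         logistic = stats::plogis(model$intercept + outer(x, b)),
         empiric  = outer(x, b, `^`),
         cloglog  = -expm1(-exp(model$intercept + outer(x, b))))
}

# Objective evaluated at a vector of slopes in one matrix operation.
objective_vec <- function(x, y, model, variance) {
  qfun <- if (variance == "bernoulli") q_bernoulli else q_wedderburn
  function(b) colSums(matrix(qfun(y, psi_outer(x, b, model)), length(y)))
}

#' Condition signalling that no model fit is possible yet
#'
#' Raised by [mle_b()] when every observed response is zero: the
#' quasi-likelihood score equation then has no interior solution, which is
#' why frequentist designs keep a model-free escalation stage until the
#' first toxicity (of any grade) is observed.
#' @noRd
no_heterogeneity <- function() {
  stop(structure(class = c("nttp_no_heterogeneity", "error", "condition"),
                 list(message = paste0(
                   "all observed responses are zero; likelihood-based ",
                   "estimation is unavailable before any toxicity is observed"),
                   call = sys.call(-1))))
}

# Bounded 1-D maximization: coarse log-spaced grid bracket, then optimize().
# obj must accept a vector of slopes.
maximize_slope <- function(obj, domain, n_grid = 128L, tol = 1e-8) {
  grid <- exp(seq(log(domain[1L]), log(domain[2L]), length.out = n_grid))
  vals <- obj(grid)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = tol)
  if (vals[i] > opt$objective) list(b = grid[i], value = vals[i])
  else list(b = opt$maximum, value = opt$objective)
}

#' Maximum quasi-likelihood estimate of the slope
#'
#' Maximizes the chosen quasi-likelihood over the model's slope domain by
#' deterministic bounded search (coarse grid bracketing followed by local
#' refinement to tolerance 1e-8). Requires heterogeneity: if all responses
#' are zero an error of class \code{"nttp_no_heterogeneity"} is raised and
#' the calling design must remain in its escalation stage.
#'
#' @inheritParams quasi_loglik
#' @param variance \code{"bernoulli"} (default) or \code{"wedderburn"}.
#' @return An object of class \code{"nttp_fit"}: list with \code{b_hat},
#'   \code{converged} (FALSE when the maximizer sits on the domain
#'   boundary), \code{objective}, \code{method}, \code{n_obs}.
#' @export
mle_b <- function(x, y, model, variance = c("bernoulli", "wedderburn")) {
  variance <- match.arg(variance)
  check_obs(x, y)
  if (all(y == 0)) no_heterogeneity()
  obj <- objective_vec(x, y, model, variance)
  opt <- maximize_slope(obj, model$slope_domain)
  edge <- min(opt$b - model$slope_domain[1L], model$slope_domain[2L] - opt$b)
  structure(list(b_hat = opt$b, converged = edge > 1e-6,
                 objective = opt$value, method = "mle",
                 variance = variance, n_obs = length(y)),
            class = "nttp_fit")
}

#' Slope prior distributions
#'
#' \code{prior_exponential(mean)} puts an exponential prior directly on the
#' slope \eqn{b} (the Bayesian quasi-CRM default, mean 1).
#' \code{prior_lognormal(mean, var)} puts a normal prior on
#' \eqn{\log b}, keeping the slope positive while allowing the usual
#' normal prior on the log-slope (default variance 1.34).
#'
#' @param mean prior mean (of \eqn{b} for exponential, of \eqn{\log b} for
#'   lognormal).
#' @param var prior variance of \eqn{\log b} (lognormal only).
#' @return A prior specification of class \code{"nttp_prior"}.
#' @export
prior_exponential <- function(mean = 1) {
  stopifnot(mean > 0)
  structure(list(type = "exponential", rate = 1 / mean), class = "nttp_prior")
}

#' @rdname prior_exponential
#' @export
prior_lognormal <- function(mean = 0, var = 1.34) {
  stopifnot(var > 0)
  structure(list(type = "lognormal", mean = mean, sd = sqrt(var)),
            class = "nttp_prior")
}

#' Posterior mean of the slope by adaptive quadrature
#'
#' Computes \eqn{E[b \mid data] = \int b L(b) g_0(b) db / \int L(b) g_0(b)
#' db}, with \eqn{L} the quasi-Bernoulli likelihood and \eqn{g_0} the prior,
#' by adaptive quadrature (relative tolerance 1e-8) over a truncation range
#' holding all but \eqn{10^{-12}} of the prior mass at each tail. For the
#' lognormal prior the integral is taken over \eqn{\beta = \log b}. Proper
#' priors make the estimate available from the first cohort, with no data
#' at all returning the prior mean.
#'
#' @inheritParams mle_b
#' @param prior an [prior_exponential()] or [prior_lognormal()].
#' @return An \code{"nttp_fit"} with \code{method = "posterior_mean"}.
#' @export
posterior_mean_b <- function(x, y, model, prior = prior_exponential(1),
                             variance = c("bernoulli", "wedderburn")) {
  variance <- match.arg(variance)
  stopifnot(inherits(prior, "nttp_prior"))
  if (length(y) == 0L) {
    loglik <- function(b) rep(0, length(b))
  } else {
    check_obs(x, y)
    loglik <- objective_vec(x, y, model, variance)
  }
  if (prior$type == "exponential") {
    lo <- stats::qexp(1e-12, prior$rate)
    hi <- stats::qexp(1 - 1e-12, prior$rate)
    log_dens <- function(b) loglik(b) + stats::dexp(b, prior$rate, log = TRUE)
    to_b <- identity
  } else {
    lo <- stats::qnorm(1e-12, prior$mean, prior$sd)
    hi <- stats::qnorm(1 - 1e-12, prior$mean, prior$sd)
    log_dens <- function(beta)
      loglik(exp(beta)) + stats::dnorm(beta, prior$mean, prior$sd, log = TRUE)
    to_b <- exp
  }
  # Stabilize: shift by the max of the log-density on a coarse grid.
  grid <- seq(lo, hi, length.out = 201L)
  shift <- max(log_dens(grid))
  if (!is.finite(shift)) stop("posterior evidence is numerically zero")
  dens <- function(t) exp(log_dens(t) - shift)
  evid <- stats::integrate(dens, lo, hi, rel.tol = 1e-8,
                           subdivisions = 400L)$value
  if (!is.finite(evid) || evid <= 0)
    stop("posterior evidence is numerically zero")
  num <- stats::integrate(function(t) to_b(t) * dens(t), lo, hi,
                          rel.tol = 1e-8, subdivisions = 400L)$value
  b_hat <- num / evid
  structure(list(b_hat = b_hat, converged = TRUE,
                 objective = log(evid) + shift, method = "posterior_mean",
                 variance = variance, prior = prior$type,
                 n_obs = length(y)),
            class = "nttp_fit")
}

#' @export
print.nttp_fit <- function(x, ...) {
  cat("Slope estimate (", x$method, "): b_hat = ",
      format(x$b_hat, digits = 6), " from ", x$n_obs, " observation(s)\n",
      sep = "")
  if (!x$converged) cat("warning: estimate at the slope-domain boundary\n")
  invisible(x)
}
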