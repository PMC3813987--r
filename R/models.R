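#' One-parameter dose-toxicity model specification
#'
#' The mean nTTP at pseudo-dose \eqn{x} is modeled by a one-parameter curve
#' \eqn{\psi(x, b)} with slope \eqn{b > 0}:
#' \describe{
#'   \item{logistic}{\eqn{\psi = 1/(1 + e^{-a - bx})}, intercept \eqn{a}
#'     fixed (default 3); the model of the quasi-likelihood CRM.}
#'   \item{empiric}{\eqn{\psi = x^b} with working-model values
#'     \eqn{x \in (0,1)}; the model of the Bayesian quasi-CRM.}
#'   \item{cloglog}{\eqn{\psi = 1 - e^{-e^{a + bx}}}, intercept fixed.}
#' }
#' Fixing the intercept leaves a single parameter to estimate, which is
#' enough for dose finding because only the ordering of doses around the
#' target, not the full curve, must be learned. An intercept of 3 is the
#' default; markedly smaller or larger values systematically shift the
#' recommended dose.
#'
#' @param link one of \code{"logistic"}, \code{"empiric"}, \code{"cloglog"}.
#' @param intercept fixed intercept \eqn{a} (ignored by the empiric model).
#' @param slope_domain positive interval searched for the slope.
#' @return An object of class \code{"nttp_model"}.
#' @export
model_spec <- function(link = c("logistic", "empiric", "cloglog"),
                       intercept = 3, slope_domain = c(1e-3, 50)) {
  link <- match.arg(link)
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            length(slope_domain) == 2L, slope_domain[1L] > 0,
            slope_domain[1L] < slope_domain[2L])
  structure(list(link = link, intercept = intercept,
                 slope_domain = as.numeric(slope_domain)),
            class = "nttp_model")
}

#' @export
print.nttp_model <- function(x, ...) {
  cat("One-parameter", x$link, "dose-toxicity model")
  if (x$link != "empiric") cat(", intercept a =", x$intercept)
  cat("\nslope domain: (", x$slope_domain[1L], ",", x$slope_domain[2L], ")\n")
  invisible(x)
}

#' Dose-toxicity mean function
#'
#' Evaluates \eqn{\psi(x, b)} for the chosen link (see [model_spec()]).
#' Strictly increasing in \eqn{x} for every \eqn{b > 0}.
#'
#' @param x pseudo-dose value(s); for the empiric model these live in (0,1).
#' @param b slope, inside the model's \code{slope_domain}.
#' @param model an [model_spec()].
#' @return Numeric vector of mean toxicity values in (0, 1).
#' @export
psi <- function(x, b, model) {
  stopifnot(inherits(model, "nttp_model"), is.numeric(b), length(b) == 1L)
  if (b < model$slope_domain[1L] || b > model$slope_domain[2L])
    stop("slope b = ", b, " outside the admissible domain (",
         model$slope_domain[1L], ", ", model$slope_domain[2L], ")")
  switch(model$link,
         logistic = stats::plogis(model$intercept + b * x),
         empiric  = x^b,
         cloglog  = -expm1(-exp(model$intercept + b * x)))
}

# Inverse link: x such that psi(x, b) = p.
psi_inverse <- function(p, b, model) {
  switch(model$link,
         logistic = (stats::qlogis(p) - model$intercept) / b,
         empiric  = p^(1 / b),
         cloglog  = (log(-log1p(-p)) - model$intercept) / b)
}

#' Pseudo-doses by backward substitution
#'
#' Converts a skeleton of prior toxicity guesses \eqn{p_{0k}} into
#' pseudo-doses \eqn{x_k} such that \eqn{\psi(x_k, b_{init}) = p_{0k}}
#' exactly: the model reproduces the clinicians' prior beliefs at the
#' initial slope. For the empiric model the pseudo-doses are the working
#' model values \eqn{p_{0k}^{1/b_{init}}} themselves when
#' \eqn{b_{init} = 1}.
#'
#' @param skeleton strictly increasing vector of prior guesses in (0, 1).
#' @param model an [model_spec()].
#' @param b_init initial slope at which the fit is exact (default 1).
#' @return Numeric vector of pseudo-doses, strictly increasing.
#' @export
backward_substitution <- function(skeleton, model, b_init = 1) {
  check_skeleton(skeleton)
  stopifnot(inherits(model, "nttp_model"))
  psi_inverse(skeleton, b_init, model)
}

check_skeleton <- function(skeleton) {
  if (any(skeleton <= 1e-6 | skeleton >= 1 - 1e-6))
    stop("skeleton values must lie in (1e-6, 1 - 1e-6)")
  if (is.unsorted(skeleton, strictly = TRUE))
    stop("skeleton must be strictly increasing")
  invisible(skeleton)
}

#' Indifference-interval skeleton calibration
#'
#' Generates a skeleton of prior toxicity guesses by the
#' indifference-interval method: the prior-guess dose \eqn{\nu_0} is
#' assigned the target \eqn{\theta^*}, and neighboring skeleton values are
#' spaced so that at every slope on the boundary between selecting two
#' adjacent doses, the two doses' modeled toxicities straddle the target at
#' exactly \eqn{\theta^* \pm \delta}. Concretely, moving up from dose
#' \eqn{k}: the boundary slope \eqn{b_k} solves
#' \eqn{\psi(x_k, b_k) = \theta^* - \delta} and the next pseudo-dose solves
#' \eqn{\psi(x_{k+1}, b_k) = \theta^* + \delta} (and symmetrically moving
#' down). Smaller \eqn{\delta} gives a tighter skeleton around the target.
#'
#' @param theta_star normalized target in (0, 1).
#' @param halfwidth indifference half-width \eqn{\delta}, with
#'   \eqn{0 < \delta < \min(\theta^*, 1 - \theta^*)}.
#' @param prior_rd prior guess of the recommended dose (index in 1..K).
#' @param K number of dose levels.
#' @param model an [model_spec()].
#' @param b_init slope at which the skeleton is read off the pseudo-doses.
#' @return Strictly increasing skeleton vector of length K with
#'   \code{skeleton[prior_rd] == theta_star}.
#' @examples
#' indifference_skeleton(0.28, 0.04, prior_rd = 3, K = 6, model_spec("logistic"))
#' @export
indifference_skeleton <- function(theta_star, halfwidth, prior_rd, K,
                                  model = model_spec("logistic"), b_init = 1) {
  stopifnot(inherits(model, "nttp_model"),
            theta_star > 0, theta_star < 1,
            prior_rd >= 1, prior_rd <= K, K >= 1)
  if (halfwidth <= 0 || halfwidth >= min(theta_star, 1 - theta_star))
    stop("'halfwidth' must satisfy 0 < halfwidth < min(theta_star, 1 - theta_star)")
  x <- numeric(K)
  x[prior_rd] <- psi_inverse(theta_star, b_init, model)
  if (prior_rd < K) for (k in prior_rd:(K - 1L)) {
    b <- boundary_slope(x[k], theta_star - halfwidth, model)
    x[k + 1L] <- psi_inverse(theta_star + halfwidth, b, model)
  }
  if (prior_rd > 1L) for (k in prior_rd:2L) {
    b <- boundary_slope(x[k], theta_star + halfwidth, model)
    x[k - 1L] <- psi_inverse(theta_star - halfwidth, b, model)
  }
  sk <- switch(model$link,
               logistic = stats::plogis(model$intercept + b_init * x),
               empiric  = x^b_init,
               cloglog  = -expm1(-exp(model$intercept + b_init * x)))
  check_skeleton(sk)
  sk
}

# Slope at which psi(x, b) = p, i.e. the inverse of psi in b at fixed x.
boundary_slope <- function(x, p, model) {
  b <- switch(model$link,
              logistic = (stats::qlogis(p) - model$intercept) / x,
              empiric  = log(p) / log(x),
              cloglog  = (log(-log1p(-p)) - model$intercept) / x)
  if (!is.finite(b) || b <= 0)
    stop("skeleton calibration hit a non-positive boundary slope; ",
         "check the target/halfwidth/intercept combination")
  b
}
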