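#' Configure a sequential dose-finding design
#'
#' Assembles everything a trial run needs: the method, the dose-toxicity
#' model and skeleton (for model-based methods), the estimation framework,
#' the normalized target, and the accrual structure.
#'
#' Methods:
#' \describe{
#'   \item{qlcrm}{quasi-likelihood CRM: one-parameter logistic model,
#'     frequentist slope estimation, Bernoulli variance by default. Runs a
#'     model-free escalation stage (one level per cohort) while all
#'     observed nTTPs are zero, and switches permanently to model-based
#'     allocation at the first nonzero score.}
#'   \item{qcrm}{Bayesian quasi-CRM: empiric model, exponential(mean 1)
#'     slope prior, model-based from the first cohort.}
#'   \item{eid}{extended isotonic design: per-dose mean nTTP isotonized by
#'     [pava()], estimates at unexplored higher doses extrapolated from the
#'     highest explored dose, threshold comparison to the target.}
#'   \item{ua}{unified approach: a t-statistic on the observations at the
#'     current dose alone moves the dose up, down, or not at all; terminal
#'     isotonic regression over explored doses picks the RD.}
#' }
#' The variants studied alongside the main methods are reachable by
#' overriding the defaults: \code{link = "cloglog"} or
#' \code{variance = "wedderburn"} on \code{qlcrm};
#' \code{inference = "frequentist"} on \code{qcrm} (empiric-frequentist);
#' \code{link = "logistic", prior = prior_lognormal()} on \code{qcrm}
#' (logistic-Bayesian).
#'
#' @param method one of \code{"qlcrm"}, \code{"qcrm"}, \code{"eid"},
#'   \code{"ua"}.
#' @param theta_star normalized toxicity target in (0, 1).
#' @param K number of dose levels.
#' @param cohort_size patients per cohort (default 3).
#' @param n_total fixed total sample size; must be a multiple of
#'   \code{cohort_size}. The trial stops when it is exhausted.
#' @param link,intercept,slope_domain model options (see [model_spec()]);
#'   defaults depend on the method.
#' @param inference \code{"frequentist"} or \code{"bayesian"}; defaults
#'   depend on the method.
#' @param variance \code{"bernoulli"} (default) or \code{"wedderburn"}.
#' @param prior slope prior for Bayesian inference (default
#'   [prior_exponential()] for the empiric model, [prior_lognormal()] for
#'   the others).
#' @param skeleton optional explicit skeleton; by default generated by
#'   [indifference_skeleton()] with the given \code{halfwidth} and
#'   \code{prior_rd}.
#' @param halfwidth,prior_rd indifference-interval calibration parameters
#'   (defaults 0.04 and dose 3).
#' @param b_init slope at which backward substitution is exact.
#' @param delta decision threshold \eqn{\Delta} of the unified approach
#'   (default 1).
#' @param start_dose first allocated dose (default 1).
#' @param rd_rule \code{"any_dose"}: the final RD may be any dose level,
#'   allocated or not (the unified approach is intrinsically restricted to
#'   explored doses); \code{"allocated_only"}: sensitivity variant
#'   restricting the RD to doses allocated during the trial.
#' @return An object of class \code{"nttp_design"}.
#' @export
design_config <- function(method = c("qlcrm", "qcrm", "eid", "ua"),
                          theta_star, K = 6L, cohort_size = 3L,
                          n_total = 36L,
                          link = NULL, intercept = 3,
                          slope_domain = c(1e-3, 50),
                          inference = NULL,
                          variance = c("bernoulli", "wedderburn"),
                          prior = NULL, skeleton = NULL,
                          halfwidth = 0.04, prior_rd = 3L, b_init = 1,
                          delta = 1, start_dose = 1L,
                          rd_rule = c("any_dose", "allocated_only")) {
  method <- match.arg(method)
  variance <- match.arg(variance)
  rd_rule <- match.arg(rd_rule)
  stopifnot(theta_star > 0, theta_star < 1, K >= 2L, cohort_size >= 1L,
            n_total >= cohort_size, start_dose >= 1L, start_dose <= K,
            delta > 0)
  if (n_total %% cohort_size != 0)
    stop("'n_total' must be a multiple of 'cohort_size'")
  model <- pseudo_doses <- NULL
  if (method %in% c("qlcrm", "qcrm")) {
    if (is.null(link)) link <- if (method == "qlcrm") "logistic" else "empiric"
    if (is.null(inference))
      inference <- if (method == "qlcrm") "frequentist" else "bayesian"
    inference <- match.arg(inference, c("frequentist", "bayesian"))
    model <- model_spec(link, intercept = intercept,
                        slope_domain = slope_domain)
    if (is.null(skeleton))
      skeleton <- indifference_skeleton(theta_star, halfwidth, prior_rd, K,
                                        model, b_init = b_init)
    check_skeleton(skeleton)
    if (length(skeleton) != K) stop("skeleton length must equal K")
    pseudo_doses <- backward_substitution(skeleton, model, b_init = b_init)
    if (inference == "bayesian" && is.null(prior))
      prior <- if (link == "empiric") prior_exponential(1) else prior_lognormal()
  } else {
    inference <- "nonparametric"
    skeleton <- prior <- NULL
  }
  structure(list(method = method, theta_star = theta_star, K = as.integer(K),
                 cohort_size = as.integer(cohort_size),
                 n_total = as.integer(n_total), model = model,
                 skeleton = skeleton, pseudo_doses = pseudo_doses,
                 inference = inference, variance = variance, prior = prior,
                 delta = delta, start_dose = as.integer(start_dose),
                 rd_rule = rd_rule),
            class = "nttp_design")
}

#' @export
print.nttp_design <- function(x, ...) {
  cat("Dose-finding design:", toupper(x$method),
      sprintf("(%s)", x$inference), "\n")
  cat("target theta* =", x$theta_star, "|", x$K, "dose levels |",
      x$n_total, "patients in cohorts of", x$cohort_size, "\n")
  if (!is.null(x$skeleton))
    cat("skeleton:", paste(format(round(x$skeleton, 3)), collapse = " "), "\n")
  if (x$method == "ua") cat("UA threshold delta =", x$delta, "\n")
  cat("final RD rule:", x$rd_rule, "\n")
  invisible(x)
}

# Fit the slope from trial history under the design's estimation framework.
# Frequentist with all-zero responses signals nttp_no_heterogeneity.
fit_slope <- function(doses, y, cfg) {
  x <- cfg$pseudo_doses[doses]
  if (cfg$inference == "frequentist")
    mle_b(x, y, cfg$model, variance = cfg$variance)
  else
    posterior_mean_b(x, y, cfg$model, prior = cfg$prior,
                     variance = cfg$variance)
}

# Model-based allocation core: closest modeled nTTP to theta*, lower dose on
# ties, capped at one level above the highest dose tried (no skipping).
model_based_next <- function(doses, y, cfg) {
  if (cfg$inference == "frequentist" && all(y == 0))
    return(min(max(doses) + 1L, cfg$K))            # stage-1 escalation
  fit <- fit_slope(doses, y, cfg)
  p_hat <- psi(cfg$pseudo_doses, fit$b_hat, cfg$model)
  k_star <- which.min(abs(p_hat - cfg$theta_star)) # ties -> lower dose
  min(k_star, max(doses) + 1L)
}

# Isotonic per-dose estimates over explored doses, with doses above the
# highest explored extrapolated from the highest explored estimate.
isotonic_estimates <- function(doses, y, K, extrapolate = TRUE) {
  explored <- sort(unique(doses))
  means <- vapply(explored, function(k) mean(y[doses == k]), 0)
  counts <- vapply(explored, function(k) sum(doses == k), 0)
  q_fit <- pava(means, counts)
  q_hat <- rep(NA_real_, K)
  q_hat[explored] <- q_fit
  if (extrapolate) {
    top <- max(explored)
    if (top < K) q_hat[(top + 1L):K] <- q_hat[top]
    bottom <- min(explored)
    if (bottom > 1L) q_hat[seq_len(bottom - 1L)] <- q_hat[bottom]
  }
  list(q_hat = q_hat, explored = explored)
}

eid_next <- function(doses, y, cfg) {
  k <- doses[length(doses)]
  iso <- isotonic_estimates(doses, y, cfg$K)
  q <- iso$q_hat
  th <- cfg$theta_star
  if (q[k] <= th) {
    if (k < cfg$K && q[k + 1L] <= th) k + 1L else k
  } else {
    if (k > 1L && q[k - 1L] > th) k - 1L else k
  }
}

ua_next <- function(doses, y, cfg) {
  k <- doses[length(doses)]
  yk <- y[doses == k]
  n_k <- length(yk)
  ybar <- mean(yk)
  s_k <- if (n_k >= 2L) stats::sd(yk) else 0
  if (s_k == 0) {
    # limit of the t-statistic as s -> 0 (and the n_k = 1 convention)
    t_k <- if (ybar < cfg$theta_star) -Inf
           else if (ybar > cfg$theta_star) Inf else 0
  } else {
    t_k <- (ybar - cfg$theta_star) / (s_k / sqrt(n_k))
  }
  if (t_k <= -cfg$delta) min(k + 1L, cfg$K)
  else if (t_k >= cfg$delta) max(k - 1L, 1L)
  else k
}

#' Next dose under a design, given the trial history
#'
#' Applies the design's allocation rule to the observations accumulated so
#' far. All methods share the no-skipping constraint: the next dose never
#' exceeds one level above the highest dose already tried.
#'
#' @param doses integer vector: the dose level of each treated patient so
#'   far, in accrual order.
#' @param y numeric vector of the corresponding nTTP responses.
#' @param cfg an [design_config()].
#' @return The dose level (in 1..K) for the next cohort.
#' @export
next_dose <- function(doses, y, cfg) {
  stopifnot(inherits(cfg, "nttp_design"), length(doses) == length(y),
            length(doses) >= 1L, all(doses >= 1L), all(doses <= cfg$K))
  switch(cfg$method,
         qlcrm = ,
         qcrm  = model_based_next(doses, y, cfg),
         eid   = eid_next(doses, y, cfg),
         ua    = ua_next(doses, y, cfg))
}

#' Recommended dose at the end of a trial
#'
#' Selects the RD from the complete trial history:
#' model-based methods refit the slope and take the dose whose modeled nTTP
#' is closest to the target (lower dose on ties), over all dose levels
#' under \code{rd_rule = "any_dose"} -- the RD may be a dose never
#' allocated -- or over allocated doses only under the
#' \code{"allocated_only"} sensitivity variant. The extended isotonic
#' design applies the same argmin to its final isotonic estimates including
#' the extrapolation to unexplored doses. The unified approach isotonizes
#' the explored doses only; if several doses tie on the estimate closest to
#' the target, the lowest is taken when that estimate exceeds the target
#' and the highest when it falls below.
#'
#' A frequentist model-based trial that ends with every response still zero
#' has no fit; the RD is then the dose that would have been allocated next
#' (the highest tried dose under \code{"allocated_only"}).
#'
#' @inheritParams next_dose
#' @return The recommended dose level.
#' @export
select_rd <- function(doses, y, cfg) {
  stopifnot(inherits(cfg, "nttp_design"), length(doses) == length(y))
  th <- cfg$theta_star
  allocated <- sort(unique(doses))
  candidates <- if (cfg$rd_rule == "allocated_only") allocated else seq_len(cfg$K)
  if (cfg$method %in% c("qlcrm", "qcrm")) {
    if (cfg$inference == "frequentist" && all(y == 0))
      return(if (cfg$rd_rule == "allocated_only") max(allocated)
             else min(max(allocated) + 1L, cfg$K))
    fit <- fit_slope(doses, y, cfg)
    p_hat <- psi(cfg$pseudo_doses, fit$b_hat, cfg$model)
    return(candidates[which.min(abs(p_hat[candidates] - th))])
  }
  if (cfg$method == "eid") {
    q <- isotonic_estimates(doses, y, cfg$K)$q_hat
    return(candidates[which.min(abs(q[candidates] - th))])
  }
  # unified approach: explored doses only, tie rules around the target
  q <- isotonic_estimates(doses, y, cfg$K, extrapolate = FALSE)$q_hat
  dist <- abs(q[allocated] - th)
  tied <- allocated[dist <= min(dist) + 1e-12]
  if (all(q[tied] < th)) max(tied) else min(tied)
  # ties above the target (or exactly on it, or straddling it) resolve to
  # the lowest tied dose; ties below the target resolve to the highest
}

#' Run one simulated dose-finding trial
#'
#' Accrues cohorts from the scenario, scores each patient's nTTP and DLT
#' status, applies the design's allocation rule between cohorts, and
#' selects the RD when the fixed sample size is exhausted. Dose levels are
#' never skipped during escalation. Fully reproducible given \code{seed}.
#'
#' @param sc an [scenario()].
#' @param cfg an [design_config()] with \code{K} equal to the scenario's.
#' @param w an [weight_matrix()].
#' @param nu normalization constant.
#' @param seed optional integer seed for the patient draws.
#' @return An object of class \code{"nttp_trial"}: list with \code{doses},
#'   \code{cohort}, \code{grades}, \code{y} (nTTP), \code{dlt},
#'   \code{recommended_dose}, \code{allocation} (per-dose patient counts),
#'   \code{stage_switch} (first model-based cohort, frequentist designs
#'   only), and the design used.
#' @export
run_trial <- function(sc, cfg, w, nu, seed = NULL) {
  stopifnot(inherits(sc, "nttp_scenario"), inherits(cfg, "nttp_design"),
            inherits(w, "nttp_weights"))
  if (sc$K != cfg$K)
    stop("scenario and design disagree on the number of dose levels")
  if (!is.null(seed)) set.seed(seed)
  n_cohorts <- cfg$n_total %/% cfg$cohort_size
  doses <- integer(0); y <- numeric(0); dlt <- logical(0)
  cohort <- integer(0); grades <- NULL
  stage_switch <- NA_integer_
  current <- cfg$start_dose
  for (cc in seq_len(n_cohorts)) {
    g <- sample_patient(sc, current, cfg$cohort_size)
    y_c <- nttp(g, w, nu)
    doses <- c(doses, rep(current, cfg$cohort_size))
    cohort <- c(cohort, rep(cc, cfg$cohort_size))
    grades <- rbind(grades, g)
    y <- c(y, y_c)
    dlt <- c(dlt, is_dlt(g, w))
    if (is.na(stage_switch) && cfg$inference == "frequentist" && any(y > 0))
      stage_switch <- cc
    if (cc < n_cohorts) current <- next_dose(doses, y, cfg)
  }
  allocation <- tabulate(doses, nbins = cfg$K)
  structure(list(doses = doses, cohort = cohort, grades = grades, y = y,
                 dlt = dlt,
                 recommended_dose = select_rd(doses, y, cfg),
                 allocation = allocation, stage_switch = stage_switch,
                 design = cfg),
            class = "nttp_trial")
}

#' @export
print.nttp_trial <- function(x, ...) {
  cat("Simulated", toupper(x$design$method), "trial:",
      length(x$y), "patients,", max(x$cohort), "cohorts\n")
  cat("dose path:",
      paste(x$doses[!duplicated(x$cohort)], collapse = " -> "), "\n")
  cat("recommended dose:", x$recommended_dose,
      "| DLTs observed:", sum(x$dlt), "\n")
  invisible(x)
}

#' @export
as.data.frame.nttp_trial <- function(x, ...) {
  data.frame(patient = seq_along(x$y), cohort = x$cohort, dose = x$doses,
             x$grades, nttp = x$y, dlt = x$dlt, row.names = NULL)
}
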