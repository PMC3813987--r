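#' Clinical importance weight matrix for graded toxicities
#'
#' Builds the weight matrix \eqn{W = \{w_{l,j}\}} giving, for each toxicity
#' type \eqn{l} and grade \eqn{j \in \{0,\dots,4\}}, the clinical importance
#' weight used by the total toxicity profile (TTP) score, together with the
#' flags marking which (type, grade) cells count as a dose-limiting toxicity
#' (DLT).
#'
#' Grade 0 always carries weight 0; weights must be nondecreasing in grade
#' within each toxicity type (lower grades are clinically less important);
#' DLT flags must be monotone in grade (once a grade is dose limiting, all
#' higher grades are). Grades that do not exist in the grading system for a
#' given toxicity are given weight 0 and a \code{FALSE} DLT flag.
#'
#' @param weights numeric L x 5 matrix of nonnegative weights, columns =
#'   grades 0..4. Row names, if present, are used as toxicity names.
#' @param dlt logical L x 5 matrix flagging dose-limiting (type, grade) cells.
#' @param toxicities character vector of L toxicity type names.
#' @return An object of class \code{"nttp_weights"}: a list with elements
#'   \code{w} (L x 5 numeric), \code{dlt} (L x 5 logical), and
#'   \code{toxicities}.
#' @seealso [ttp()], [is_dlt()], [example_weight_matrix()]
#' @examples
#' w <- weight_matrix(
#'   weights = rbind(renal = c(0, 0.5, 0.75, 1, 1.5)),
#'   dlt     = rbind(renal = c(FALSE, FALSE, FALSE, TRUE, TRUE)))
#' ttp(c(3), w)
#' @export
weight_matrix <- function(weights, dlt, toxicities = rownames(weights)) {
  weights <- as.matrix(weights)
  dlt <- as.matrix(dlt)
  if (ncol(weights) != 5L || ncol(dlt) != 5L)
    stop("'weights' and 'dlt' must have 5 columns (grades 0..4)")
  if (!identical(dim(weights), dim(dlt)))
    stop("'weights' and 'dlt' must have the same dimensions")
  L <- nrow(weights)
  if (L < 1L) stop("at least one toxicity type is required")
  if (is.null(toxicities)) toxicities <- paste0("tox", seq_len(L))
  if (length(toxicities) != L) stop("'toxicities' must name every row")
  storage.mode(weights) <- "double"
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and nonnegative")
  if (any(weights[, 1L] != 0))
    stop("grade 0 must carry weight 0 for every toxicity type")
  if (any(apply(weights, 1L, function(r) any(diff(r) < 0))))
    stop("weights must be nondecreasing in grade within each toxicity type")
  storage.mode(dlt) <- "logical"
  if (any(is.na(dlt))) stop("'dlt' must not contain NA")
  # once dose limiting, all higher grades are dose limiting
  if (any(apply(dlt, 1L, function(r) any(diff(as.integer(r)) < 0))))
    stop("DLT flags must be monotone in grade within each toxicity type")
  if (any(dlt & weights == 0 & col(dlt) > 1L))
    stop("a zero-weight grade (nonexistent in the grading system) cannot be a DLT")
  dimnames(weights) <- dimnames(dlt) <-
    list(toxicities, paste0("grade", 0:4))
  structure(list(w = weights, dlt = dlt, toxicities = toxicities),
            class = "nttp_weights")
}

#' @export
print.nttp_weights <- function(x, ...) {
  cat("Toxicity weight matrix (", length(x$toxicities), " types x grades 0-4)\n",
      sep = "")
  m <- x$w
  flag <- ifelse(x$dlt, "*", "")
  out <- matrix(paste0(format(m, digits = 3), flag), nrow(m),
                dimnames = dimnames(m))
  print(out, quote = FALSE)
  cat("* dose-limiting (type, grade) cell; TTP_max =",
      format(ttp_max(x), digits = 4), "\n")
  invisible(x)
}

# Coerce patient grades into an n x L integer matrix and validate the range.
as_grade_matrix <- function(grades, w) {
  L <- length(w$toxicities)
  if (is.null(dim(grades))) {
    if (length(grades) %% L != 0)
      stop("grade vector length must be a multiple of the number of toxicity types (",
           L, ")")
    grades <- matrix(grades, ncol = L, byrow = TRUE)
  }
  grades <- as.matrix(grades)
  if (ncol(grades) != L)
    stop("expected ", L, " grade columns, got ", ncol(grades))
  if (any(is.na(grades)) || any(grades != round(grades)))
    stop("grades must be integers in 0..4")
  if (any(grades == 5))
    stop("grade 5 (death) is outside the score's grade space [0,4]; ",
         "such events require a safety-committee decision, not the algorithm")
  if (any(grades < 0 | grades > 4))
    stop("grades must lie in 0..4")
  storage.mode(grades) <- "integer"
  grades
}

#' Total toxicity profile (TTP) score
#'
#' Computes the TTP of one or more patients: the Euclidean norm of the
#' weights of the toxicities experienced,
#' \deqn{TTP = \sqrt{\sum_l w_{l, g_l}^2},}
#' where \eqn{g_l} is the observed grade of toxicity type \eqn{l}. Unlike an
#' arithmetic sum of weights, the norm keeps a single severe toxicity from
#' being matched by an accumulation of mild ones, while still increasing
#' with every additional event.
#'
#' @param grades integer vector of length L (one patient), a vector whose
#'   length is a multiple of L (patients stacked row-wise), or an n x L
#'   matrix/data.frame of grades in 0..4.
#' @param w a [weight_matrix()].
#' @return Numeric vector of TTP scores, one per patient.
#' @examples
#' ex <- example_weight_matrix()
#' ttp(c(4, 4, 4), ex$weights)   # most severe possible profile
#' ttp(c(3, 0, 0), ex$weights)   # single grade-3 renal event
#' @export
ttp <- function(grades, w) {
  stopifnot(inherits(w, "nttp_weights"))
  g <- as_grade_matrix(grades, w)
  wt <- w$w[cbind(as.vector(col(g)), as.vector(g) + 1L)]
  sqrt(rowSums(matrix(wt * wt, nrow(g))))
}

#' Normalized total toxicity profile (nTTP)
#'
#' Divides the TTP by the normalization constant \eqn{\nu = TTP_{max} +
#' \epsilon}, mapping the score into \eqn{[0, 1)} so it can be treated as a
#' fractional event under a quasi-Bernoulli likelihood. The slack
#' \eqn{\epsilon} leaves room to integrate, mid-trial, a severe toxicity
#' that was not weighted a priori.
#'
#' @inheritParams ttp
#' @param nu positive normalization constant, strictly greater than
#'   \code{ttp_max(w)}.
#' @return Numeric vector of nTTP scores in \eqn{[0, 1)}.
#' @examples
#' ex <- example_weight_matrix()
#' nttp(c(3, 0, 0), ex$weights, ex$nu)  # 1 / 2.5 = 0.4
#' @export
nttp <- function(grades, w, nu) {
  stopifnot(is.numeric(nu), length(nu) == 1L, nu > 0)
  if (nu <= ttp_max(w))
    stop("'nu' must exceed ttp_max(w) = ", format(ttp_max(w), digits = 6),
         " so that nTTP < 1")
  ttp(grades, w) / nu
}

#' Most severe possible TTP under a weight matrix
#'
#' Because weights are nondecreasing in grade, the maximum over all
#' \eqn{5^L} toxicity profiles is attained at the all-grade-4 profile.
#'
#' @inheritParams ttp
#' @return The maximal TTP score, a single nonnegative number.
#' @export
ttp_max <- function(w) {
  stopifnot(inherits(w, "nttp_weights"))
  sqrt(sum(w$w[, 5L]^2))
}

#' Dose-limiting toxicity indicator
#'
#' A patient has a DLT when any observed (type, grade) cell is flagged as
#' dose limiting in the weight matrix.
#'
#' @inheritParams ttp
#' @return Logical vector, one entry per patient.
#' @examples
#' ex <- example_weight_matrix()
#' is_dlt(c(3, 0, 0), ex$weights)  # grade-3 renal: TRUE
#' is_dlt(c(0, 0, 3), ex$weights)  # grade-3 hematological: FALSE
#' @export
is_dlt <- function(grades, w) {
  stopifnot(inherits(w, "nttp_weights"))
  g <- as_grade_matrix(grades, w)
  fl <- w$dlt[cbind(as.vector(col(g)), as.vector(g) + 1L)]
  rowSums(matrix(fl, nrow(g))) > 0
}

#' Elicit the target TTP from classified hypothetical cohorts
#'
#' Before a trial, clinicians classify a set of hypothetical patient cohorts
#' into decisions to escalate, repeat, or de-escalate the dose. Once the
#' classification is consistent -- every escalate cohort has a lower mean TTP
#' than every repeat cohort, and every repeat cohort a lower mean TTP than
#' every de-escalate cohort -- the target \eqn{\theta} is the mean of the
#' cohort-mean TTPs over the repeat cohorts, and the normalized target is
#' \eqn{\theta^* = \theta / \nu}.
#'
#' @param cohorts a list; each element is a list with components
#'   \code{grades} (patients x L matrix, or vector for one patient) and
#'   \code{decision} (one of \code{"escalate"}, \code{"repeat"},
#'   \code{"de-escalate"}).
#' @inheritParams nttp
#' @return A list with \code{theta} (raw TTP scale), \code{theta_star}
#'   (normalized), and \code{cohort_means} (data frame of per-cohort mean
#'   TTPs and decisions).
#' @export
elicit_target <- function(cohorts, w, nu) {
  stopifnot(inherits(w, "nttp_weights"), length(cohorts) >= 1L)
  decisions <- vapply(cohorts, function(co)
    match.arg(co$decision, c("escalate", "repeat", "de-escalate")), "")
  means <- vapply(cohorts, function(co) mean(ttp(co$grades, w)), 0)
  if (!any(decisions == "repeat"))
    stop("at least one cohort classified as 'repeat' is required")
  hi_esc <- suppressWarnings(max(means[decisions == "escalate"]))
  lo_rep <- min(means[decisions == "repeat"])
  hi_rep <- max(means[decisions == "repeat"])
  lo_des <- suppressWarnings(min(means[decisions == "de-escalate"]))
  bad <- character(0)
  if (any(decisions == "escalate") && hi_esc >= lo_rep)
    bad <- c(bad, sprintf(
      "escalate cohort mean TTP %.4g >= repeat cohort mean TTP %.4g",
      hi_esc, lo_rep))
  if (any(decisions == "de-escalate") && hi_rep >= lo_des)
    bad <- c(bad, sprintf(
      "repeat cohort mean TTP %.4g >= de-escalate cohort mean TTP %.4g",
      hi_rep, lo_des))
  if (length(bad))
    stop("inconsistent cohort classification: ", paste(bad, collapse = "; "),
         ". Re-elicit the ordering before computing the target.")
  theta <- mean(means[decisions == "repeat"])
  list(theta = theta, theta_star = theta / nu,
       cohort_means = data.frame(cohort = seq_along(cohorts),
                                 decision = decisions, mean_ttp = means))
}

#' Example three-toxicity weight matrix
#'
#' A reconstructed weight matrix for three independent toxicity types
#' (renal, neurological, hematological) that satisfies the published
#' constraints of the motivating worked example: a single grade-3 renal,
#' grade-3 neurological, or grade-4 hematological toxicity scores 1; a
#' single grade-4 renal or neurological toxicity scores 1.5; two concurrent
#' grade-2 toxicities score about the same as a single DLT; the maximal
#' profile scores \eqn{\sqrt{5.5} \approx 2.345}. The grade-1/2 weights are
#' not uniquely pinned down by those constraints; the values here are one
#' admissible reconstruction and can be overridden by supplying your own
#' [weight_matrix()].
#'
#' DLT is defined as grade 3-4 renal or neurological toxicity, or grade 4
#' hematological toxicity. The normalization constant is \eqn{\nu = 2.5} and
#' the elicited normalized target is \eqn{\theta^* = 0.28}.
#'
#' @return A list with components \code{weights} (an \code{nttp_weights}
#'   object), \code{nu}, and \code{theta_star}.
#' @examples
#' ex <- example_weight_matrix()
#' round(ttp(c(4, 4, 4), ex$weights), 2)
#' @export
example_weight_matrix <- function() {
  w <- weight_matrix(
    weights = rbind(
      renal          = c(0, 0.5, 0.75, 1.00, 1.5),
      neurological   = c(0, 0.5, 0.75, 1.00, 1.5),
      hematological  = c(0, 0.0, 0.50, 0.75, 1.0)),
    dlt = rbind(
      renal          = c(FALSE, FALSE, FALSE, TRUE,  TRUE),
      neurological   = c(FALSE, FALSE, FALSE, TRUE,  TRUE),
      hematological  = c(FALSE, FALSE, FALSE, FALSE, TRUE)))
  list(weights = w, nu = 2.5, theta_star = 0.28)
}
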