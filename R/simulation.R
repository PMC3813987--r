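#' Operating characteristics of a design by replicated trials
#'
#' Runs \code{n_reps} independent trials of the design under a scenario and
#' aggregates the usual operating characteristics: the percentage of
#' correct selection (PCS, trials recommending the scenario's true RD), the
#' per-dose recommendation and allocation percentages, the distribution of
#' recommendations relative to the true RD (RD-1, RD, RD+1, ...), per-trial
#' DLT counts, and the pooled per-patient nTTP scores.
#'
#' Each replicate runs on its own deterministically derived seed, so
#' replicate \code{r} can be reproduced in isolation with
#' \code{run_trial(..., seed = trial_seed(seed, r))}.
#'
#' @inheritParams run_trial
#' @param n_reps number of replicated trials.
#' @param seed base integer seed.
#' @return An object of class \code{"nttp_sim"}: list with \code{n_reps},
#'   \code{pcs}, \code{pcs_se} (binomial Monte-Carlo standard error, in
#'   percentage points), \code{recommendation_pct}, \code{allocation_pct},
#'   \code{rd_offsets} (named percentage table), \code{dlt_counts},
#'   \code{nttp_samples}, \code{recommended} (per-trial RD), and the design
#'   and scenario used.
#' @export
simulate_design <- function(sc, cfg, w, nu, n_reps = 1000L, seed = 1L) {
  stopifnot(inherits(sc, "nttp_scenario"), inherits(cfg, "nttp_design"))
  n_reps <- as.integer(n_reps)
  recommended <- integer(n_reps)
  allocation <- matrix(0L, n_reps, cfg$K)
  dlt_counts <- integer(n_reps)
  nttp_samples <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    tr <- run_trial(sc, cfg, w, nu, seed = trial_seed(seed, r))
    recommended[r] <- tr$recommended_dose
    allocation[r, ] <- tr$allocation
    dlt_counts[r] <- sum(tr$dlt)
    nttp_samples[[r]] <- tr$y
  }
  rec_pct <- 100 * tabulate(recommended, nbins = cfg$K) / n_reps
  alloc_pct <- 100 * colSums(allocation) / sum(allocation)
  names(rec_pct) <- names(alloc_pct) <- paste0("d", seq_len(cfg$K))
  pcs <- pcs_se <- NA_real_
  rd_offsets <- NULL
  if (!is.null(sc$true_rd)) {
    pcs <- 100 * mean(recommended == sc$true_rd)
    pcs_se <- 100 * sqrt(pcs / 100 * (1 - pcs / 100) / n_reps)
    off <- recommended - sc$true_rd
    rng <- seq(min(off), max(off))
    rd_offsets <- vapply(rng, function(o) 100 * mean(off == o), 0)
    names(rd_offsets) <- ifelse(rng == 0, "RD",
                                ifelse(rng < 0, paste0("RD", rng),
                                       paste0("RD+", rng)))
  }
  structure(list(n_reps = n_reps, pcs = pcs, pcs_se = pcs_se,
                 recommendation_pct = rec_pct, allocation_pct = alloc_pct,
                 rd_offsets = rd_offsets, dlt_counts = dlt_counts,
                 nttp_samples = unlist(nttp_samples),
                 recommended = recommended, design = cfg, scenario = sc),
            class = "nttp_sim")
}

# Deterministic per-replicate substream seed, kept inside 32-bit range.
trial_seed <- function(seed, r) {
  (as.integer(seed) + 9973L * as.integer(r)) %% 2147483647L
}

#' @export
print.nttp_sim <- function(x, ...) {
  cat("Simulation:", toupper(x$design$method), "x", x$n_reps, "trials of",
      x$design$n_total, "patients\n")
  if (!is.na(x$pcs))
    cat(sprintf("PCS at true RD (dose %d): %.1f%% (MC SE %.1f)\n",
                x$scenario$true_rd, x$pcs, x$pcs_se))
  cat("recommendation %:",
      paste(sprintf("%.1f", x$recommendation_pct), collapse = " "), "\n")
  cat("allocation %:    ",
      paste(sprintf("%.1f", x$allocation_pct), collapse = " "), "\n")
  cat(sprintf("mean DLTs per trial: %.2f | mean nTTP per patient: %.3f\n",
              mean(x$dlt_counts), mean(x$nttp_samples)))
  invisible(x)
}

#' @export
plot.nttp_sim <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  graphics::barplot(x$recommendation_pct, ylab = "recommendation %",
                    xlab = "dose level",
                    main = toupper(x$design$method), ...)
  graphics::boxplot(x$nttp_samples, ylab = "nTTP",
                    main = "per-patient toxicity scores")
  invisible(x)
}

#' Convergence of the percentage of correct selection with sample size
#'
#' Repeats [simulate_design()] over a grid of total sample sizes, holding
#' everything else fixed, to check that the design's PCS approaches 100%
#' as the trial grows. Designs whose PCS plateaus well below 100% (as the
#' purely isotonic extrapolating design does in many configurations) are
#' suspect even at realistic sample sizes.
#'
#' @inheritParams simulate_design
#' @param n_grid integer vector of total sample sizes, each a multiple of
#'   the design's cohort size.
#' @return A data frame with one row per sample size: \code{n}, \code{pcs},
#'   \code{se}.
#' @export
convergence_study <- function(sc, cfg, w, nu, n_grid = seq(15L, 99L, by = 12L),
                              n_reps = 500L, seed = 1L) {
  stopifnot(length(n_grid) >= 1L)
  if (any(n_grid %% cfg$cohort_size != 0))
    stop("every entry of 'n_grid' must be a multiple of the cohort size")
  if (is.null(sc$true_rd))
    stop("the scenario needs 'true_rd' to score correct selection")
  rows <- lapply(n_grid, function(n) {
    cfg_n <- cfg
    cfg_n$n_total <- as.integer(n)
    sm <- simulate_design(sc, cfg_n, w, nu, n_reps = n_reps, seed = seed)
    data.frame(n = n, pcs = sm$pcs, se = sm$pcs_se)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("nttp_convergence", class(out))
  out
}

#' @export
plot.nttp_convergence <- function(x, ...) {
  graphics::plot(x$n, x$pcs, type = "b", ylim = c(0, 100),
                 xlab = "total sample size n", ylab = "PCS (%)", ...)
  graphics::arrows(x$n, x$pcs - 2 * x$se, x$n, x$pcs + 2 * x$se,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Tabulate several simulation summaries side by side
#'
#' Builds a method-by-dose table of recommendation and allocation
#' percentages (one decimal place), the layout used to compare designs on
#' a common scenario.
#'
#' @param sims a list of \code{"nttp_sim"} objects sharing the same number
#'   of dose levels.
#' @param labels row labels (default: each design's method name).
#' @return A data frame with columns \code{label}, \code{pcs},
#'   \code{rec_d1..rec_dK}, \code{alloc_d1..alloc_dK}.
#' @export
summarize_tables <- function(sims, labels = NULL) {
  stopifnot(length(sims) >= 1L,
            all(vapply(sims, inherits, TRUE, "nttp_sim")))
  K <- length(sims[[1L]]$recommendation_pct)
  if (!all(vapply(sims, function(s) length(s$recommendation_pct), 0L) == K))
    stop("all summaries must share the number of dose levels")
  if (is.null(labels))
    labels <- vapply(sims, function(s) toupper(s$design$method), "")
  rows <- lapply(seq_along(sims), function(i) {
    s <- sims[[i]]
    row <- data.frame(label = labels[i], pcs = round(s$pcs, 1))
    rec <- as.data.frame(t(round(s$recommendation_pct, 1)))
    names(rec) <- paste0("rec_d", seq_len(K))
    alloc <- as.data.frame(t(round(s$allocation_pct, 1)))
    names(alloc) <- paste0("alloc_d", seq_len(K))
    cbind(row, rec, alloc)
  })
  do.call(rbind, rows)
}
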