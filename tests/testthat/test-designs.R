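cfg_ql <- design_config("qlcrm", theta_star = ex_theta)
cfg_qc <- design_config("qcrm", theta_star = ex_theta)
cfg_ei <- design_config("eid", theta_star = ex_theta)
cfg_ua <- design_config("ua", theta_star = ex_theta)

test_that("design configuration enforces its invariants", {
  expect_error(design_config("qlcrm", theta_star = 0.28, n_total = 35),
               "multiple")
  expect_error(design_config("qlcrm", theta_star = 1.2), "theta_star")
  expect_equal(cfg_ql$skeleton[3], 0.28)
  expect_equal(length(cfg_ql$pseudo_doses), 6L)
  expect_equal(cfg_qc$model$link, "empiric")
  expect_equal(cfg_qc$prior$type, "exponential")
  # variants: empiric-frequentist and logistic-Bayesian configurations
  expect_equal(design_config("qcrm", theta_star = 0.28,
                             inference = "frequentist")$inference,
               "frequentist")
  lb <- design_config("qcrm", theta_star = 0.28, link = "logistic",
                      prior = prior_lognormal())
  expect_equal(lb$prior$type, "lognormal")
})

test_that("QLCRM escalates one level per cohort while no toxicity is seen", {
  expect_equal(next_dose(rep(1L, 3), rep(0, 3), cfg_ql), 2L)
  expect_equal(next_dose(rep(1:5, each = 3), rep(0, 15), cfg_ql), 6L)
  # ceiling: stays at the top dose
  expect_equal(next_dose(rep(c(1:6, 6L), each = 3), rep(0, 21), cfg_ql), 6L)
})

test_that("model-based allocation caps escalation at one untried level", {
  # toxicity low enough that the unconstrained argmin is far above the
  # highest tried dose
  doses <- rep(1L, 3)
  y <- c(0.02, 0, 0.03)
  fit <- mle_b(cfg_ql$pseudo_doses[doses], y, cfg_ql$model)
  p_hat <- psi(cfg_ql$pseudo_doses, fit$b_hat, cfg_ql$model)
  k_unconstrained <- which.min(abs(p_hat - ex_theta))
  expect_gt(k_unconstrained, 2)               # would skip without the cap
  expect_equal(next_dose(doses, y, cfg_ql), 2L)
})

test_that("QCRM is model-based from the first cohort and deterministic", {
  d1 <- next_dose(rep(1L, 3), rep(0, 3), cfg_qc)
  expect_equal(d1, next_dose(rep(1L, 3), rep(0, 3), cfg_qc))
  expect_lte(d1, 2L)   # no-skip cap after a single cohort at dose 1
  # grid oracle: decision matches a brute-force posterior plug-in argmin
  doses <- rep(c(1L, 2L), each = 3)
  y <- c(0, 0.1, 0, 0.2, 0.3, 0.15)
  fit <- posterior_mean_b(cfg_qc$pseudo_doses[doses], y, cfg_qc$model,
                          prior = cfg_qc$prior)
  p_hat <- cfg_qc$skeleton^fit$b_hat
  want <- min(which.min(abs(p_hat - ex_theta)), 3L)
  expect_equal(next_dose(doses, y, cfg_qc), want)
})

test_that("binary responses reproduce the classic likelihood-CRM decisions", {
  # hand-traced four-cohort history with 0/1 outcomes; the quasi-Bernoulli
  # objective collapses to the binomial log-likelihood, so decisions must
  # match an independently coded binary CRM
  doses <- rep(c(1L, 2L, 3L, 3L), each = 3)
  y <- c(0, 0, 0,  0, 0, 1,  1, 0, 1,  0, 1, 0)
  x <- cfg_ql$pseudo_doses
  binary_crm_next <- function(doses, y) {
    ll <- function(b) sum(dbinom(y, 1, plogis(3 + b * x[doses]), log = TRUE))
    b_hat <- optimize(ll, c(1e-3, 50), maximum = TRUE, tol = 1e-10)$maximum
    min(which.min(abs(plogis(3 + b_hat * x) - ex_theta)), max(doses) + 1L)
  }
  for (i in c(6, 9, 12)) {
    d_i <- doses[seq_len(i)]; y_i <- y[seq_len(i)]
    expect_equal(next_dose(d_i, y_i, cfg_ql), binary_crm_next(d_i, y_i))
  }
})

test_that("EID pools violators and applies the threshold rule", {
  # three explored doses, monotone means, current dose under the target and
  # the next (unexplored) estimate extrapolated from the highest explored
  doses <- rep(c(1L, 2L, 3L), each = 3)
  y <- c(0, 0, 0.1,  0.1, 0.2, 0,  0.2, 0.25, 0.15)
  # means: 0.033, 0.1, 0.2 -- all <= 0.28, extrapolated q4 = 0.2 <= 0.28
  expect_equal(next_dose(doses, y, cfg_ei), 4L)

  # current dose above target but the lower estimate is not: stay
  y2 <- c(0, 0, 0.1,  0.1, 0.2, 0,  0.5, 0.45, 0.2)
  expect_equal(next_dose(doses, y2, cfg_ei), 3L)

  # current and lower both above target: de-escalate
  y3 <- c(0, 0, 0.1,  0.4, 0.5, 0.2,  0.5, 0.45, 0.2)
  expect_equal(next_dose(doses, y3, cfg_ei), 2L)

  # violated monotonicity is pooled before the decision: hand computation
  doses4 <- rep(c(1L, 2L, 3L), each = 3)
  y4 <- c(0.35, 0.4, 0.3,  0.1, 0.2, 0.15,  0.2, 0.1, 0.15)
  means <- tapply(y4, doses4, mean)              # 0.35, 0.15, 0.15: violation
  pooled <- pava(as.numeric(means), c(3, 3, 3))  # hand: rep(0.2167, 3)
  expect_equal(pooled, rep(mean(y4), 3))
  # pooled estimate 0.2167 <= theta* at current and next: escalate
  expect_equal(next_dose(doses4, y4, cfg_ei), 4L)
})

test_that("UA moves by the t-statistic on the current dose only", {
  # all responses at the current dose equal to the target: stay
  expect_equal(next_dose(rep(2L, 3), rep(ex_theta, 3), cfg_ua), 2L)
  # no toxicity with spread zero: strong evidence below target, escalate
  expect_equal(next_dose(rep(2L, 3), rep(0, 3), cfg_ua), 3L)
  # direct formula: T = (ybar - theta*) / (s / sqrt(n))
  y <- c(0.05, 0.1, 0.15)
  t_k <- (mean(y) - ex_theta) / (sd(y) / sqrt(3))
  expect_lt(t_k, -1)
  expect_equal(next_dose(rep(2L, 3), y, cfg_ua), 3L)
  y_hot <- c(0.5, 0.55, 0.6)
  expect_equal(next_dose(rep(2L, 3), y_hot, cfg_ua), 1L)
  # |T| < Delta: stay
  y_mid <- c(0.1, 0.3, 0.45)
  expect_true(abs((mean(y_mid) - ex_theta) / (sd(y_mid) / sqrt(3))) < 1)
  expect_equal(next_dose(rep(2L, 3), y_mid, cfg_ua), 2L)
  # history at other doses does not matter
  expect_equal(next_dose(c(rep(1L, 3), rep(2L, 3)), c(0.9, 0.8, 0.85, y),
                         cfg_ua), 3L)
  # floors and ceilings
  expect_equal(next_dose(rep(1L, 3), y_hot, cfg_ua), 1L)
  expect_equal(next_dose(rep(6L, 3), rep(0, 3), cfg_ua), 6L)
})

test_that("final RD selection honors each method's rules", {
  # UA ties above the target resolve to the lowest tied dose,
  # ties below to the highest
  cfg <- cfg_ua
  doses <- rep(c(1L, 2L, 3L), each = 3)
  y_above <- c(0.4, 0.3, 0.35,  0.3, 0.35, 0.4,  0.35, 0.3, 0.4)
  # all three pooled to the same value above theta*
  expect_equal(select_rd(doses, y_above, cfg), 1L)
  y_below <- c(0.2, 0.1, 0.15,  0.1, 0.15, 0.2,  0.15, 0.1, 0.2)
  expect_equal(select_rd(doses, y_below, cfg), 3L)

  # model-based any_dose may recommend a dose never allocated
  doses2 <- rep(1L, 6)
  y2 <- c(0, 0.05, 0.02, 0, 0.04, 0.01)
  rd_any <- select_rd(doses2, y2, cfg_ql)
  cfg_alloc <- design_config("qlcrm", theta_star = ex_theta,
                             rd_rule = "allocated_only")
  rd_alloc <- select_rd(doses2, y2, cfg_alloc)
  expect_equal(rd_alloc, 1L)
  expect_gt(rd_any, rd_alloc)   # unconstrained argmin was never allocated

  # all-zero frequentist trial recommends the next dose it would allocate
  expect_equal(select_rd(rep(1:6, each = 3), rep(0, 18), cfg_ql), 6L)
  expect_equal(select_rd(rep(1L, 3), rep(0, 3), cfg_ql), 2L)
})

test_that("trials never skip dose levels and are seed-reproducible", {
  set.seed(17)
  for (rep in 1:25) {
    sc <- random_scenario(true_rd = 3L)
    cfg <- switch(1L + rep %% 4, cfg_ql, cfg_qc, cfg_ei, cfg_ua)
    tr <- run_trial(sc, cfg, ex_w, ex_nu, seed = 1000 + rep)
    path <- tr$doses[!duplicated(tr$cohort)]
    for (i in seq_along(path)[-1])
      expect_lte(path[i], max(path[seq_len(i - 1)]) + 1L)
    expect_equal(sum(tr$allocation), cfg$n_total)
  }
  sc <- benchmark_scenario("C")
  t1 <- run_trial(sc, cfg_ql, ex_w, ex_nu, seed = 5)
  t2 <- run_trial(sc, cfg_ql, ex_w, ex_nu, seed = 5)
  expect_identical(t1$doses, t2$doses)
  expect_identical(t1$y, t2$y)
  expect_identical(t1$recommended_dose, t2$recommended_dose)
})

test_that("a zero-toxicity scenario walks straight up and stays at the top", {
  sc0 <- degenerate_scenario(c(0L, 0L, 0L))
  tr <- run_trial(sc0, cfg_ql, ex_w, ex_nu, seed = 1)
  expect_equal(tr$doses[!duplicated(tr$cohort)],
               c(1:6, rep(6L, 6)))
  expect_equal(tr$allocation, c(3L, 3L, 3L, 3L, 3L, 21L))
  expect_true(is.na(tr$stage_switch))
  # deterministic scenario: identical record whatever the seed
  sc_d <- degenerate_scenario(c(2L, 1L, 0L))
  ta <- run_trial(sc_d, cfg_qc, ex_w, ex_nu, seed = 1)
  tb <- run_trial(sc_d, cfg_qc, ex_w, ex_nu, seed = 999)
  expect_identical(ta$doses, tb$doses)
  expect_identical(ta$recommended_dose, tb$recommended_dose)
})

test_that("appending a maximally toxic cohort never raises the next dose", {
  # coherence probe for the model-based designs
  set.seed(31)
  sc <- benchmark_scenario("C")
  for (cfg in list(cfg_ql, cfg_qc)) {
    tr <- run_trial(sc, cfg, ex_w, ex_nu, seed = 77)
    d0 <- next_dose(tr$doses, tr$y, cfg)
    cur <- tr$doses[length(tr$doses)]
    y_max <- rep(ttp_max(ex_w) / ex_nu, 3)
    d1 <- next_dose(c(tr$doses, rep(cur, 3)), c(tr$y, y_max), cfg)
    expect_lte(d1, d0)
  }
})

test_that("the no-heterogeneity condition never escapes the trial engine", {
  sc0 <- degenerate_scenario(c(0L, 0L, 0L))
  expect_no_error(run_trial(sc0, cfg_ql, ex_w, ex_nu, seed = 3))
  expect_no_error(run_trial(sc0, design_config("qcrm", theta_star = 0.28,
                                               inference = "frequentist"),
                            ex_w, ex_nu, seed = 3))
})
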