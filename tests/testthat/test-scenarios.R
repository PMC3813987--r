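test_that("profile distribution multiplies independent grade probabilities", {
  # degenerate: all mass on the zero profile
  sc0 <- degenerate_scenario(c(0L, 0L, 0L))
  p <- profile_distribution(sc0, 1)
  expect_equal(sum(p), 1)
  expect_equal(p[1], 1)  # first profile of the grid is (0,0,0)

  # L = 1: the distribution is the matrix row itself
  sc1 <- random_scenario(K = 4, L = 1)
  expect_equal(profile_distribution(sc1, 2), as.numeric(sc1$P[[1]][2, ]),
               ignore_attr = TRUE)

  # uniform rows: every one of the 125 profiles has probability 0.2^3
  scu <- scenario(setNames(rep(list(matrix(0.2, 6, 5)), 3), letters[1:3]))
  expect_equal(profile_distribution(scu, 3), rep(0.008, 125),
               ignore_attr = TRUE)

  expect_error(profile_distribution(scu, 7), "dose")
})

test_that("profile distribution marginals recover the input rows", {
  set.seed(41)
  sc <- random_scenario()
  grid <- attr(profile_distribution(sc, 1), "profiles")
  for (k in c(1, 4, 6)) {
    p <- profile_distribution(sc, k)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    for (l in 1:3) {
      marg <- vapply(0:4, function(j) sum(p[grid[, l] == j]), 0)
      expect_equal(marg, as.numeric(sc$P[[l]][k, ]), tolerance = 1e-12)
    }
  }
})

test_that("exact moments match trivial cases and Monte-Carlo sampling", {
  sc0 <- degenerate_scenario(c(0L, 0L, 0L))
  mom0 <- scenario_moments(sc0, ex_w, ex_nu)
  expect_equal(mom0$mean_nttp, rep(0, 6))
  expect_equal(mom0$p_dlt, rep(0, 6))

  # point mass on grade 3 of a single toxicity: nTTP = 1/2.5, always a DLT
  w1 <- weight_matrix(rbind(renal = c(0, 0.5, 0.75, 1, 1.5)),
                      rbind(renal = c(FALSE, FALSE, FALSE, TRUE, TRUE)))
  sc3 <- degenerate_scenario(c(3L), K = 2)
  mom3 <- scenario_moments(sc3, w1, 2.5)
  expect_equal(mom3$mean_nttp, rep(0.4, 2))
  expect_equal(mom3$p_dlt, rep(1, 2))

  # sampling oracle: enumeration agrees with the empirical moments
  set.seed(99)
  sc <- random_scenario()
  mom <- scenario_moments(sc, ex_w, ex_nu)
  n <- 2e5
  g <- sample_patient(sc, 4, n)
  y <- nttp(g, ex_w, ex_nu)
  d <- is_dlt(g, ex_w)
  expect_lt(abs(mean(y) - mom$mean_nttp[4]), 3 * sd(y) / sqrt(n))
  expect_lt(abs(mean(d) - mom$p_dlt[4]),
            3 * sqrt(mom$p_dlt[4] * (1 - mom$p_dlt[4]) / n))
})

test_that("patient sampling is reproducible and matches the rows", {
  sc <- degenerate_scenario(c(2L, 0L, 4L))
  expect_equal(unname(sample_patient(sc, 1, 5)),
               matrix(rep(c(2L, 0L, 4L), each = 5), 5))
  set.seed(7); a <- sample_patient(random_scenario(), 1, 10)
  set.seed(7); b <- sample_patient(random_scenario(), 1, 10)
  expect_identical(a, b)
  # empirical grade frequencies approach the generating row
  set.seed(11)
  sc2 <- random_scenario()
  g <- sample_patient(sc2, 2, 1e5)
  for (l in 1:3) {
    freq <- tabulate(g[, l] + 1L, 5) / 1e5
    p <- as.numeric(sc2$P[[l]][2, ])
    se <- sqrt(pmax(p * (1 - p), 1e-12) / 1e5)
    expect_true(all(abs(freq - p) < 3 * se + 1e-4))
  }
})

test_that("unimodality diagnostics flag shape violations", {
  good <- benchmark_scenario("F")
  expect_equal(nrow(validate_unimodal(good)), 0L)

  P <- matrix(0.2, 4, 5)
  P[, 2] <- c(0.1, 0.3, 0.2, 0.4)            # two local maxima at grade 1
  P[, 3] <- c(0.3, 0.1, 0.2, 0.0)
  P <- P / rowSums(P)
  # renormalization can perturb other columns; grade-1 stays bimodal
  bad <- scenario(list(t1 = P))
  v <- validate_unimodal(bad)
  expect_true(any(v$grade == 1))

  mono <- scenario(list(t1 = rbind(c(0.9, 0.1, 0, 0, 0),
                                   c(0.7, 0.2, 0.1, 0, 0),
                                   c(0.5, 0.2, 0.2, 0.1, 0))))
  expect_equal(nrow(validate_unimodal(mono)), 0L)
})

test_that("calibration hits target mean-nTTP rows and rejects infeasible ones", {
  # fixed point: calibrating to the moments of a calibrated scenario
  tgt <- c(0.05, 0.12, 0.20, 0.28, 0.35, 0.42)
  sc <- calibrate_scenario(tgt, ex_w, ex_nu)
  mom <- scenario_moments(sc, ex_w, ex_nu)
  expect_equal(mom$mean_nttp, tgt, tolerance = 1e-6)
  expect_equal(nrow(validate_unimodal(sc)), 0L)

  sc2 <- calibrate_scenario(mom$mean_nttp, ex_w, ex_nu)
  expect_equal(scenario_moments(sc2, ex_w, ex_nu)$mean_nttp, tgt,
               tolerance = 1e-6)

  # benchmark row F is reproduced within the stated tolerance
  tg <- benchmark_targets()
  rowF <- tg[tg$scenario == "F", ]
  scF <- benchmark_scenario("F")
  expect_true(all(abs(scenario_moments(scF, ex_w, ex_nu)$mean_nttp -
                        rowF$mean_nttp) < 0.01))
  expect_equal(scF$true_rd, 4L)

  # mean nTTP beyond the all-grade-4 score is unreachable
  expect_error(calibrate_scenario(c(0.95), ex_w, ex_nu), "achievable range")
})

test_that("mean nTTP increases with dose for stochastically ordered scenarios", {
  sc <- calibrate_scenario(seq(0.05, 0.45, length.out = 6), ex_w, ex_nu)
  mom <- scenario_moments(sc, ex_w, ex_nu)
  expect_false(is.unsorted(mom$mean_nttp))
  expect_false(is.unsorted(mom$p_dlt))
})

test_that("scenario validation rejects malformed probability matrices", {
  expect_error(scenario(list(matrix(0.3, 2, 5))), "sum to 1")
  m <- matrix(0.2, 2, 5); m[1, 1] <- -0.2; m[1, 2] <- 0.6
  expect_error(scenario(list(m)), "nonnegative")
  expect_error(scenario(list(a = matrix(0.2, 2, 5), b = matrix(0.2, 3, 5))),
               "share")
})
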