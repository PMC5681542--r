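# Logic sampling, rejection queries, the exact Gaussian oracle and
# do-style interventions.

ab_net <- function() {
  gbn_network(list(
    A = list(intercept = 0, coefficients = numeric(0), residual_sd = 1),
    B = list(intercept = 2, coefficients = c(A = 3), residual_sd = 1)
  ))
}

test_that("forward samples follow the local models and the seed contract", {
  net <- gbn_network(list(
    x = list(intercept = 3, coefficients = numeric(0), residual_sd = 2)
  ))
  s <- logic_sample(net, 1e5, seed = 1)
  expect_lt(abs(mean(s$x) - 3), 3 * 2 / sqrt(1e5))
  expect_lt(abs(stats::sd(s$x) - 2), 0.05)

  s2 <- logic_sample(net, 1e5, seed = 1)
  expect_identical(s, s2)

  chain <- gbn_network(list(
    A = list(intercept = 0, coefficients = numeric(0), residual_sd = 1),
    B = list(intercept = 0, coefficients = c(A = 2), residual_sd = 1)
  ))
  d <- logic_sample(chain, 5e4, seed = 2)
  expect_lt(abs(stats::cov(d$A, d$B) / stats::var(d$A) - 2), 0.05)
})

test_that("implied moments match hand computations", {
  mom <- implied_moments(ab_net())
  expect_equal(unname(mom$mean), c(0, 2), tolerance = 1e-12)
  expect_equal(mom$cov["B", "B"], 10, tolerance = 1e-12) # 3^2 * 1 + 1
  expect_equal(mom$cov["A", "B"], 3, tolerance = 1e-12)
  expect_equal(mom$cov["A", "A"], 1, tolerance = 1e-12)
})

test_that("exact conditioning reproduces closed-form Gaussian results", {
  net <- ab_net()
  # empty evidence returns the implied marginals unchanged
  m0 <- exact_conditional(net, NULL)
  expect_equal(m0$mean, implied_moments(net)$mean, tolerance = 1e-12)

  # conditioning B on A equals the local model (leaf with observed parent)
  mB <- exact_conditional(net, c(A = 1.3))
  expect_equal(unname(mB$mean["B"]), 2 + 3 * 1.3, tolerance = 1e-12)
  expect_equal(unname(mB$cov["B", "B"]), 1, tolerance = 1e-9)

  # conditioning A on B: textbook bivariate-normal regression
  mA <- exact_conditional(net, c(B = 4))
  expect_equal(unname(mA$mean["A"]), 3 / 10 * (4 - 2), tolerance = 1e-12)
  expect_equal(unname(mA$cov["A", "A"]), 1 - 9 / 10, tolerance = 1e-9)

  expect_error(exact_conditional(net, c(A = Inf)), "finite")
  expect_error(exact_conditional(net, c(Z = 1)), "existing nodes")
})

test_that("sampled moments agree with implied moments on random networks", {
  n <- 2e4
  for (seed in 1:10) {
    net <- rand_net(seed, N = sample(3:9, 1))
    mom <- implied_moments(net)
    s <- logic_sample(net, n, seed = seed + 500)
    for (v in mom$nodes) {
      se <- sqrt(mom$cov[v, v] / n)
      expect_lt(abs(mean(s[[v]]) - mom$mean[v]), 4 * se)
    }
  }
})

test_that("rejection queries match the exact oracle and normalise", {
  net <- gbn_network(list(
    A = list(intercept = 0, coefficients = numeric(0), residual_sd = 1),
    B = list(intercept = 0, coefficients = c(A = 1), residual_sd = 1)
  ))
  # normalisation: an always-true event has probability one
  q0 <- conditional_query(net, event = list(A = c(-Inf, Inf)), n = 1000,
                          seed = 1)
  expect_equal(q0$estimate, 1.0)

  # symmetry of a standard normal
  q1 <- conditional_query(net, event = list(A = c(0, Inf)), n = 2e5,
                          seed = 2)
  expect_lt(abs(q1$estimate - 0.5), 3 * q1$mc_se)

  # interval evidence against the quadrature oracle
  q2 <- conditional_query(net, event = list(B = c(1, Inf)),
                          evidence = list(A = c(0.9, 1.1)), n = 1e5,
                          seed = 3)
  exact <- exact_query(net, "B", c(1, Inf), "A", c(0.9, 1.1))
  expect_lt(abs(q2$estimate - exact), 3 * q2$mc_se)
  expect_equal(q2$type, "probability")

  # parameter query: truncated-normal conditional mean
  q3 <- conditional_query(net, event = "B", evidence = list(A = c(1, 2)),
                          n = 1e5, seed = 4)
  a <- stats::dnorm(1) - stats::dnorm(2)
  b <- stats::pnorm(2) - stats::pnorm(1)
  expect_lt(abs(q3$estimate - a / b), 4 * q3$mc_se)
  expect_equal(q3$type, "mean")

  # impossible evidence yields an explicit no-match result
  q4 <- conditional_query(net, event = list(B = c(0, 1)),
                          evidence = list(A = c(50, 60)), n = 1000, seed = 5)
  expect_false(q4$matched)
  expect_true(is.na(q4$estimate))
  expect_equal(q4$n_matched_evidence, 0L)

  # point evidence on a continuous node is refused
  expect_error(conditional_query(net, event = list(B = c(0, 1)),
                                 evidence = list(A = 1), n = 10),
               "probability zero")
})

test_that("rejection estimates are unbiased across seeds", {
  net <- ab_net()
  exact <- exact_query(net, "B", c(4, Inf), "A", c(0, 1))
  est <- vapply(1:100, function(s) {
    conditional_query(net, event = list(B = c(4, Inf)),
                      evidence = list(A = c(0, 1)), n = 2000,
                      seed = s)$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - exact), 3 * stats::sd(est) / sqrt(100))
})

test_that("binary nodes are queried on their thresholded values", {
  net <- gbn_network(list(
    Treatment = list(intercept = 0.4, coefficients = numeric(0),
                     residual_sd = 0.49),
    Growth = list(intercept = 0.2, coefficients = c(Treatment = 0.5),
                  residual_sd = 0.4)
  ), binary_nodes = c("Treatment", "Growth"))
  q <- conditional_query(net, event = list(Growth = 1),
                         evidence = list(Treatment = 1), n = 2e4, seed = 9)
  expect_true(q$estimate >= 0 && q$estimate <= 1)
  # equality evidence on a binary node is legal; on a continuous one it is not
  expect_gt(q$n_matched_evidence, 0)
})

test_that("fixing a node removes parental influence and is idempotent", {
  net <- gbn_network(list(
    P = list(intercept = 0, coefficients = numeric(0), residual_sd = 1),
    M = list(intercept = 1, coefficients = c(P = 4), residual_sd = 1),
    Y = list(intercept = 0, coefficients = c(M = 2), residual_sd = 1)
  ))
  fixed <- intervene_fix(net, "M", 0)
  s <- logic_sample(fixed, 5000, seed = 3)
  expect_lt(max(abs(s$M)), 5 * 1e-6)
  expect_equal(nrow(arcs(fixed$dag)), 1L) # only M -> Y remains

  # former parents have no influence under extreme evidence
  q <- conditional_query(fixed, event = "M", evidence = list(P = c(2, 4)),
                         n = 2e4, seed = 4)
  expect_lt(abs(q$estimate - 0), 1e-4)

  # idempotent and commuting across distinct nodes
  expect_identical(intervene_fix(fixed, "M", 0)$locals, fixed$locals)
  ab <- intervene_fix(intervene_fix(net, "M", 0), "P", 1)
  ba <- intervene_fix(intervene_fix(net, "P", 1), "M", 0)
  expect_identical(ab$locals, ba$locals)
  expect_identical(ab$dag$amat, ba$dag$amat)
})
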