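# Cross-validated predictive correlation and classification error.

# Hand-built near-deterministic 9-node truth: every feature is downstream
# of observed variables, so predictions from "all other variables" should
# be near-perfect when residual noise sits at the floor.
noiseless_truth <- function(sd = 1e-6) {
  gbn_network(list(
    dT = list(intercept = 6.5, coefficients = numeric(0),
              residual_sd = 1.4),
    Treatment = list(intercept = 0.46, coefficients = numeric(0),
                     residual_sd = 0.5),
    Growth = list(intercept = -0.8, coefficients = c(dT = 0.2),
                  residual_sd = 0.5),
    dANB = list(intercept = 0, coefficients = c(Treatment = 2, dT = -0.3),
                residual_sd = sd),
    dPPPM = list(intercept = 0, coefficients = c(dT = 0.5, Growth = 1.5),
                 residual_sd = sd),
    dIMPA = list(intercept = 0, coefficients = c(dANB = 2, dPPPM = -1.5),
                 residual_sd = sd),
    dCoA = list(intercept = 1, coefficients = c(dT = 0.6, Treatment = 2),
                residual_sd = sd),
    dGoPg = list(intercept = 0, coefficients = c(dCoA = 1.2),
                 residual_sd = sd),
    dCoGo = list(intercept = 0, coefficients = c(dGoPg = 0.8, dPPPM = -1.1),
                 residual_sd = sd)
  ), binary_nodes = c("Treatment", "Growth"))
}

test_that("classification error counts mismatches exactly", {
  expect_equal(classification_error(c(1, 0, 1), c(1, 0, 1)), 0.0)
  expect_equal(classification_error(c(1, 0, 1), c(0, 1, 0)), 1.0)
  expect_equal(classification_error(c(1, 0, 1, 0), c(1, 0, 0, 1)), 0.5)
  expect_equal(classification_error(0, 1), 1.0)
  expect_error(classification_error(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(classification_error(numeric(0), numeric(0)), "empty")
  expect_error(classification_error(c(1, NA), c(1, 0)), "missing")
})

test_that("noiseless relations are learned and predicted almost perfectly", {
  tab <- simulate_rate_table(noiseless_truth(), 300, seed = 8)
  cons <- malocclusion_constraints(colnames(tab))
  cv <- cross_validate(tab, cons, k = 10, seed = 1)
  downstream <- c("dANB", "dPPPM", "dIMPA", "dCoA", "dGoPg", "dCoGo")
  for (v in downstream) {
    expect_gte(cv$predictive_correlation[[v]], 0.99)
  }
  # folds partition the rows with sizes differing by at most one
  sizes <- table(cv$fold_assignments)
  expect_equal(length(cv$fold_assignments), nrow(tab))
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sum(sizes), nrow(tab))
})

test_that("a pure-noise feature shows no signal beyond the fold-mean artifact", {
  # pooled leave-fold-out prediction of an unpredictable variable is
  # anti-correlated with the held-out fold by construction: the predictor
  # is (minus) the fold's own contribution to the training mean, giving an
  # expected pooled correlation of -1/sqrt(fold size), not 0
  truth <- make_truth(77, noise_scale = 1)
  tab <- simulate_rate_table(truth, 300, seed = 12)
  set.seed(13)
  tab$dNoise <- stats::rnorm(300)
  cons <- malocclusion_constraints(colnames(tab))
  cv <- cross_validate(tab, cons, k = 10, seed = 2)
  artifact <- -1 / sqrt(300 / 10)
  expect_lt(abs(cv$predictive_correlation[["dNoise"]] - artifact), 0.15)
})

test_that("predictive correlation is the pooled-pair Pearson correlation", {
  tab <- simulate_rate_table(make_truth(5), 120, seed = 3)
  cons <- malocclusion_constraints(colnames(tab))
  cv <- cross_validate(tab, cons, k = 5, seed = 4)
  for (v in names(cv$predictive_correlation)) {
    pv <- cv$pairs[cv$pairs$variable == v, ]
    expect_equal(cv$predictive_correlation[[v]],
                 pearson_r(pv$observed, pv$predicted), tolerance = 1e-12)
  }
  expect_equal(cv$classification_error,
               1 - mean((cv$pairs$predicted[cv$pairs$variable == "Growth"] >=
                           0.5) ==
                          cv$pairs$observed[cv$pairs$variable == "Growth"]),
               tolerance = 1e-12)
})

test_that("row order does not systematically change CV metrics", {
  truth <- make_truth(9, noise_scale = 0.8)
  tab <- simulate_rate_table(truth, 300, seed = 21)
  cons <- malocclusion_constraints(colnames(tab))
  diffs <- vapply(1:6, function(s) {
    set.seed(1000 + s)
    perm <- sample(nrow(tab))
    a <- cross_validate(tab, cons, seed = s)
    b <- cross_validate(tab[perm, ], cons, seed = s)
    mean(a$predictive_correlation[c("dCoGo", "dGoPg", "dCoA")] -
           b$predictive_correlation[c("dCoGo", "dGoPg", "dCoA")])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("predictive correlation rises as generating noise falls", {
  ladder <- c(2, 1, 0.5, 0.1)
  means <- vapply(ladder, function(ns) {
    tab <- simulate_rate_table(make_truth(31, noise_scale = ns), 250,
                               seed = 17)
    cv <- cross_validate(tab, malocclusion_constraints(colnames(tab)),
                         seed = 18)
    mean(cv$predictive_correlation[c("dANB", "dIMPA", "dPPPM", "dCoA",
                                     "dGoPg", "dCoGo")])
  }, numeric(1))
  expect_true(all(diff(means) > -0.01)) # monotone up to small jitter
  expect_gt(means[4], means[1])
})

test_that("missing prognosis rows are excluded from the Growth metric only", {
  tab <- simulate_rate_table(make_truth(41, noise_scale = 0.5), 200,
                             seed = 6)
  tab$Growth[tab$Treatment == 1] <- NA_real_
  cons <- malocclusion_constraints(colnames(tab))
  cv <- suppressMessages(cross_validate(tab, cons, k = 5, seed = 7))
  growth_pairs <- cv$pairs[cv$pairs$variable == "Growth", ]
  expect_equal(nrow(growth_pairs), sum(!is.na(tab$Growth)))
  # feature predictions still cover every row
  expect_equal(nrow(cv$pairs[cv$pairs$variable == "dCoGo", ]), nrow(tab))
  expect_false(anyNA(cv$pairs$predicted))
})
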