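# Ground-truth construction and cohort simulation.

test_that("sampled truths are deterministic and tier-respecting", {
  t1 <- make_truth(11)
  t2 <- make_truth(11)
  expect_identical(t1$locals, t2$locals)
  expect_identical(t1$dag$amat, t2$dag$amat)

  for (seed in 1:10) {
    tr <- make_truth(seed)
    a <- tr$dag$amat
    # whitelisted arcs always present
    expect_equal(a["dANB", "dIMPA"], 1L)
    expect_equal(a["dPPPM", "dIMPA"], 1L)
    expect_equal(a["dT", "Growth"], 1L)
    # nothing into the exogenous tier, no feature into the prognosis
    expect_equal(sum(a[, "dT"]), 0L)
    expect_equal(sum(a[, "Treatment"]), 0L)
    features <- setdiff(rownames(a), c("dT", "Treatment", "Growth"))
    expect_equal(sum(a[features, "Growth"]), 0L)
    # coefficient magnitudes within the stated band
    for (f in features) {
      co <- tr$locals[[f]]$coefficients
      co <- co[names(co) != "Treatment"]
      if (length(co) > 0L) expect_true(all(abs(co) >= 1 & abs(co) <= 5))
    }
  }
})

test_that("null construction removes every treatment effect", {
  tr <- make_truth(3, regime_effects = 0, growth_treatment_effect = 0)
  expect_equal(sum(tr$dag$amat["Treatment", ]), 0L)
  # with effects on, Treatment points at the configured features
  tr2 <- make_truth(3, regime_effects = c(dCoA = 2, dANB = 2))
  expect_equal(tr2$dag$amat["Treatment", "dCoA"], 1L)
  expect_equal(tr2$dag$amat["Treatment", "dANB"], 1L)
  expect_equal(unname(tr2$locals$dCoA$coefficients["Treatment"]), 2)
})

test_that("simulated cohorts satisfy every cohort invariant", {
  for (seed in c(1, 99)) {
    coh <- simulate_cohort(generator_config(n_patients = 80, seed = seed))
    expect_silent(validate_cohort(coh))
    expect_true(all(coh$age_t2 > coh$age_t1))
    expect_true(all(coh$age_t1 >= 6 & coh$age_t1 <= 19))
    dt <- coh$age_t2 - coh$age_t1
    expect_true(all(dt >= 4 & dt <= 9))
  }
  # blanking option: prognosis missing exactly for treated patients
  blanked <- simulate_cohort(generator_config(n_patients = 80, seed = 1,
                                              blank_growth_treated = TRUE))
  expect_true(all(is.na(blanked$growth[blanked$treated == 1])))
  expect_false(anyNA(blanked$growth[blanked$treated == 0]))
})

test_that("the realised treated fraction matches the design probability", {
  cfg <- generator_config(n_patients = 1e4, seed = 23)
  coh <- simulate_cohort(cfg)
  p <- cfg$treated_fraction
  expect_lt(abs(mean(coh$treated) - p), 3 * sqrt(p * (1 - p) / 1e4))
})

test_that("differences of a simulated cohort reproduce the drawn deltas", {
  cfg <- generator_config(n_patients = 120, seed = 31)
  coh <- simulate_cohort(cfg)
  tab <- compute_differences(coh)
  # visit-2 minus visit-1 must equal the deltas that were added in
  for (f in ceph_features()) {
    expect_lt(max(abs(coh[[paste0(f, "_t2")]] - coh[[paste0(f, "_t1")]] -
                        tab[[paste0("d", f)]])), 1e-12)
  }
})

test_that("simulated feature means match the implied moments", {
  # strip the prognosis of feature children so the generative law is the
  # implied all-Gaussian one up to the binary coding of the roots
  base <- make_truth(7, noise_scale = 1)
  locals <- lapply(base$locals, function(lm) {
    keep <- names(lm$coefficients) != "Growth"
    list(intercept = lm$intercept, coefficients = lm$coefficients[keep],
         residual_sd = lm$residual_sd)
  })
  truth <- gbn_network(locals, binary_nodes = c("Treatment", "Growth"))
  attr(truth, "growth_rule") <- attr(base, "growth_rule")
  cfg <- generator_config(n_patients = 2e4, seed = 71, truth = truth,
                          growth_link = "threshold")
  tab <- compute_differences(simulate_cohort(cfg))
  mom <- implied_moments(truth)
  n <- nrow(tab)
  for (f in c("dANB", "dIMPA", "dPPPM", "dCoA", "dGoPg", "dCoGo")) {
    se <- sqrt(mom$cov[f, f] / n)
    expect_lt(abs(mean(tab[[f]]) - mom$mean[f]), 4 * se)
  }
})

test_that("the packaged fixture cohort regenerates from its recorded seed", {
  path <- system.file("extdata", "synthetic_cohort_143.csv",
                      package = "cephnet")
  expect_true(nzchar(path))
  fixture <- read_cohort(path)
  expect_equal(nrow(fixture), 143L)
  regen <- simulate_cohort(generator_config(seed = 1143))
  cols <- setdiff(names(fixture), "id")
  expect_lt(max(abs(as.matrix(regen[cols]) - as.matrix(fixture[cols])),
                na.rm = TRUE), 1e-10)
  expect_identical(as.character(regen$id), as.character(fixture$id))

  truth_path <- system.file("extdata", "synthetic_truth_143.json",
                            package = "cephnet")
  truth <- read_fit_json(truth_path)
  expect_identical(arcs(truth$dag), arcs(make_truth(1143)$dag))
})

test_that("OLS recovery stays within its theoretical standard errors", {
  for (seed in 1:10) {
    truth <- make_truth(seed, noise_scale = 0.5)
    d <- logic_sample(truth, 1e4, seed = seed + 3000L)
    fit <- fit_ols(truth$dag, d)
    mom <- implied_moments(truth)
    for (v in truth$dag$nodes) {
      gen <- truth$locals[[v]]$coefficients
      if (length(gen) == 0L) next
      est <- fit$locals[[v]]$coefficients[names(gen)]
      S <- mom$cov[names(gen), names(gen), drop = FALSE]
      se <- truth$locals[[v]]$residual_sd * sqrt(diag(solve(S)) / 1e4)
      expect_true(all(abs(est - gen) <= 4 * se))
    }
  }
})

test_that("end-to-end recovery finds the true skeleton on a strong cohort", {
  truth <- make_truth(500, noise_scale = 0.3)
  cfg <- generator_config(n_patients = 1000, seed = 500, truth = truth,
                          growth_link = "threshold")
  tab <- compute_differences(simulate_cohort(cfg))
  cons <- malocclusion_constraints(colnames(tab))
  g <- averaged_network(tab, cons, R = 100, seed = 501)
  expect_lte(shd(g, truth$dag), 1L)
})
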