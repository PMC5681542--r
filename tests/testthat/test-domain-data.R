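# Cohort ingestion, validation, atlas adjustment and the raw-to-difference
# transform.

test_that("well-formed cohort CSVs ingest and malformed ones are rejected", {
  df <- make_cohort_df(3)
  coh <- read_cohort(as_cohort_file(df))
  expect_s3_class(coh, "ceph_cohort")
  expect_equal(nrow(coh), 3L)
  expect_identical(attr(coh, "provenance"), "raw")

  expect_error(read_cohort(as_cohort_file(df[setdiff(names(df), "CoGo_t1")])),
               "CoGo_t1")

  bad <- df
  bad$age_t1[2] <- 9
  bad$age_t2[2] <- 9
  expect_error(read_cohort(as_cohort_file(bad)), "P02")

  # prognosis may be missing only for treated patients
  orphan <- df
  orphan$growth[orphan$treated == 0][1] <- NA
  expect_error(read_cohort(as_cohort_file(orphan)), "untreated")

  expect_error(read_cohort(tempfile()), "not found")
})

test_that("patients with more than two recorded visits can keep (first, last)", {
  df <- make_cohort_df(3)
  extra <- df[1, ]
  extra$age_t1 <- df$age_t1[1] + 2
  extra$age_t2 <- df$age_t2[1] + 3
  extra$ANB_t2 <- 99
  stacked <- rbind(df, extra)
  expect_error(read_cohort(as_cohort_file(stacked)), "duplicated")
  coh <- read_cohort(as_cohort_file(stacked), multiple = "first_last")
  expect_equal(nrow(coh), 3L)
  row <- coh[coh$id == df$id[1], ]
  expect_equal(row$age_t1, df$age_t1[1]) # earliest first visit
  expect_equal(row$age_t2, df$age_t2[1] + 3) # latest second visit
  expect_equal(row$ANB_t2, 99)
})

test_that("differences follow the two-visit definitions and fixed layout", {
  df <- make_cohort_df(4)
  df$age_t1[1] <- 8
  df$age_t2[1] <- 15
  df$CoA_t1[1] <- 85
  df$CoA_t2[1] <- 99
  df$ANB_t2[2] <- df$ANB_t1[2] # identical at both visits
  coh <- read_cohort(as_cohort_file(df))
  tab <- compute_differences(coh)

  expect_identical(colnames(tab),
                   c("dT", "Treatment", "Growth", "dANB", "dIMPA", "dPPPM",
                     "dCoA", "dGoPg", "dCoGo"))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$dT[1], 7)
  expect_equal(tab$dCoA[1], 14)
  expect_equal(tab$dANB[2], 0)
  expect_true(all(tab$dT > 0))
  expect_identical(rownames(tab), as.character(coh$id))
})

test_that("visit-2 values rebuild exactly from visit-1 plus differences", {
  coh <- simulate_cohort(generator_config(n_patients = 60, seed = 42))
  tab <- compute_differences(coh)
  for (f in ceph_features()) {
    rebuilt <- coh[[paste0(f, "_t1")]] + tab[[paste0("d", f)]]
    expect_lt(max(abs(rebuilt - coh[[paste0(f, "_t2")]])), 1e-12)
  }
  expect_lt(max(abs(coh$age_t1 + tab$dT - coh$age_t2)), 1e-12)
})

test_that("difference transform is permutation-equivariant over patients", {
  coh <- simulate_cohort(generator_config(n_patients = 30, seed = 7))
  tab <- compute_differences(coh)
  set.seed(99)
  perm <- sample(nrow(coh))
  tab_perm <- compute_differences(coh[perm, ])
  expect_equal(as.data.frame(tab_perm), as.data.frame(tab)[perm, ])
})

test_that("atlas adjustment subtracts interpolated reference values", {
  ref_df <- expand.grid(feature = ceph_features(), age = c(5, 30),
                        stringsAsFactors = FALSE)
  ref_df$value <- 0

  df <- make_cohort_df(2)
  coh <- read_cohort(as_cohort_file(df))

  # identically-zero reference leaves the cohort unchanged
  adj0 <- adjust_by_reference(coh, reference_table(ref_df))
  expect_equal(as.data.frame(adj0)[-1], as.data.frame(coh)[-1])
  expect_identical(attr(adj0, "provenance"), "adjusted")

  # reference equal to every observed value zeroes everything
  self_ref <- NULL
  for (f in ceph_features()) {
    self_ref <- rbind(self_ref,
                      data.frame(feature = f,
                                 age = c(coh$age_t1, coh$age_t2),
                                 value = c(coh[[paste0(f, "_t1")]],
                                           coh[[paste0(f, "_t2")]])))
  }
  adj_self <- adjust_by_reference(coh, reference_table(self_ref))
  for (f in ceph_features()) {
    expect_lt(max(abs(adj_self[[paste0(f, "_t1")]])), 1e-12)
    expect_lt(max(abs(adj_self[[paste0(f, "_t2")]])), 1e-12)
  }

  # midpoint interpolation: (ANB, 8y) = 4, (ANB, 10y) = 6, age 9, ANB 5 -> 0
  one <- make_cohort_df(1)
  one$age_t1 <- 9
  one$age_t2 <- 15
  one$ANB_t1 <- 5
  mid_ref <- expand.grid(feature = ceph_features(), age = c(8, 10, 20),
                         stringsAsFactors = FALSE)
  mid_ref$value <- 0
  mid_ref$value[mid_ref$feature == "ANB"] <- c(4, 6, 6)
  adj <- adjust_by_reference(read_cohort(as_cohort_file(one)),
                             reference_table(mid_ref))
  expect_equal(adj$ANB_t1, 0, tolerance = 1e-12)

  # extrapolation is a coverage error naming patient and feature
  narrow <- expand.grid(feature = ceph_features(), age = c(8.5, 9),
                        stringsAsFactors = FALSE)
  narrow$value <- 0
  expect_error(adjust_by_reference(coh, reference_table(narrow)), "P01.*ANB")
})

test_that("adjustment and differencing commute", {
  coh <- simulate_cohort(generator_config(n_patients = 25, seed = 5))
  ages <- seq(4, 32, by = 2)
  set.seed(11)
  ref_df <- do.call(rbind, lapply(ceph_features(), function(f) {
    data.frame(feature = f, age = ages,
               value = cumsum(stats::rnorm(length(ages))))
  }))
  ref <- reference_table(ref_df)
  tab_adj <- compute_differences(adjust_by_reference(coh, ref))
  tab_raw <- compute_differences(coh)
  for (f in ceph_features()) {
    r1 <- stats::approx(ages, ref_df$value[ref_df$feature == f],
                        xout = coh$age_t1)$y
    r2 <- stats::approx(ages, ref_df$value[ref_df$feature == f],
                        xout = coh$age_t2)$y
    expect_lt(max(abs(tab_adj[[paste0("d", f)]] -
                        (tab_raw[[paste0("d", f)]] - (r2 - r1)))), 1e-9)
  }
})
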