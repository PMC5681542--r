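# Ground-truth network construction and two-visit cohort simulation.
# The generator emulates the study design the analysis assumes: ~143
# growing Class III patients, 66 of them treated, two visits several years
# apart, six craniofacial difference variables driven by a known
# tier-respecting linear-Gaussian network, and a binary prognosis observed
# for untreated patients.

.rate_nodes <- function() {
  c("dT", "Treatment", "Growth",
    "dANB", "dIMPA", "dPPPM", "dCoA", "dGoPg", "dCoGo")
}

#' Sample a tier-respecting ground-truth network
#'
#' Draws a random DAG over the nine rate-of-change variables that satisfies
#' the clinical tier constraints (nothing into `dT` or `Treatment`, no
#' feature into `Growth`) and always contains the whitelisted arcs
#' `dANB -> dIMPA`, `dPPPM -> dIMPA` and `dT -> Growth`. Arc coefficients
#' have magnitude in `[1, 5]` with random signs; feature residual standard
#' deviations are proportional to `noise_scale`.
#'
#' `Treatment` affects the craniofacial features only through
#' `regime_effects`, a named vector of per-feature additive treatment
#' coefficients: with `regime_effects = 0` (and
#' `growth_treatment_effect = 0`) the treated and untreated generating laws
#' are identical. The default places the treatment effect on `dCoA`
#' (maxillary length, the target of maxillary expansion) and `dANB` (the
#' sagittal imbalance the facemask therapy aims to stabilise).
#'
#' The prognosis is governed by a logistic rule
#' `P(Growth = 1) = plogis(g0 + g_dT * dT + g_Tr * Treatment)` stored in
#' attribute `growth_rule`; the fitted-network representation carries its
#' local linearisation so the implied Gaussian moments stay well defined.
#'
#' @param seed Integer seed; equal seeds give identical truths.
#' @param regime_effects Named numeric vector of Treatment -> feature
#'   coefficients (a bare scalar is applied to `dCoA` and `dANB`), or 0
#'   for no treatment effect on the features.
#' @param noise_scale Residual standard deviation scale of the feature
#'   nodes (> 0).
#' @param growth_treatment_effect Logistic coefficient of `Treatment` in
#'   the prognosis rule (0 removes the `Treatment -> Growth` arc).
#' @param p_arc Probability of each optional arc (feature-feature,
#'   `dT` -> feature, `Growth` -> feature).
#' @return A `"gbn_fit"` ground truth with `binary_nodes = c("Treatment",
#'   "Growth")` and attribute `growth_rule`.
#' @export
make_truth <- function(seed, regime_effects = c(dCoA = 2, dANB = 2),
                       noise_scale = 1, growth_treatment_effect = 0.6,
                       p_arc = 0.4) {
  stopifnot(noise_scale > 0)
  set.seed(as.integer(seed))
  nodes <- .rate_nodes()
  features <- setdiff(nodes, c("dT", "Treatment", "Growth"))
  if (length(regime_effects) == 1L && is.null(names(regime_effects))) {
    regime_effects <- c(dCoA = unname(regime_effects),
                        dANB = unname(regime_effects))
  }
  regime_effects <- regime_effects[regime_effects != 0]
  if (length(regime_effects) > 0L &&
      !all(names(regime_effects) %in% features)) {
    stop("regime_effects must be named by feature", call. = FALSE)
  }

  # random feature order consistent with the whitelisted v-structure
  repeat {
    ford <- sample(features)
    if (which(ford == "dANB") < which(ford == "dIMPA") &&
        which(ford == "dPPPM") < which(ford == "dIMPA")) break
  }

  rnd_coef <- function(k) stats::runif(k, 1, 5) *
    sample(c(-1, 1), k, replace = TRUE)

  treated_p <- 66 / 143
  gamma <- c(intercept = -1.4, dT = 0.18,
             Treatment = growth_treatment_effect)
  p_bar <- stats::plogis(gamma["intercept"] + gamma["dT"] * 6.5 +
                           gamma["Treatment"] * treated_p)
  gslope <- unname(gamma[c("dT", "Treatment")] * p_bar * (1 - p_bar))
  g_parents <- c("dT", if (growth_treatment_effect != 0) "Treatment")
  g_coef <- stats::setNames(gslope[seq_along(g_parents)], g_parents)
  g_int <- unname(p_bar - sum(g_coef * c(6.5, treated_p)[seq_along(g_parents)]))

  locals <- list(
    dT = list(intercept = 6.5, coefficients = numeric(0),
              residual_sd = 5 / sqrt(12)),
    Treatment = list(intercept = treated_p, coefficients = numeric(0),
                     residual_sd = sqrt(treated_p * (1 - treated_p))),
    Growth = list(intercept = g_int, coefficients = g_coef,
                  residual_sd = sqrt(p_bar * (1 - p_bar)))
  )

  for (i in seq_along(ford)) {
    f <- ford[i]
    pa <- character(0)
    # whitelisted v-structure
    if (f == "dIMPA") pa <- c("dANB", "dPPPM")
    # optional upstream-feature parents
    extra <- setdiff(ford[seq_len(i - 1L)], pa)
    pa <- c(pa, extra[stats::runif(length(extra)) < p_arc])
    # optional exogenous/prognosis parents
    if (stats::runif(1) < p_arc + 0.2) pa <- c(pa, "dT")
    if (stats::runif(1) < p_arc) pa <- c(pa, "Growth")
    coef <- stats::setNames(rnd_coef(length(pa)), pa)
    if (f %in% names(regime_effects)) {
      coef <- c(coef, Treatment = unname(regime_effects[f]))
    }
    locals[[f]] <- list(intercept = stats::runif(1, -2, 2),
                        coefficients = coef,
                        residual_sd = noise_scale * stats::runif(1, 0.8, 1.2))
  }

  truth <- gbn_network(locals[nodes],
                       binary_nodes = c("Treatment", "Growth"))
  attr(truth, "growth_rule") <- gamma
  truth
}

#' Configuration for the synthetic cohort generator
#'
#' Collects the study-design parameters of [simulate_cohort()]: cohort
#' size 143 with 66 treated patients, first-visit age normal with mean 8
#' and sd 1 year (truncated to 6-19), between-visit gap uniform on 4-9
#' years, and baseline first-visit feature distributions on
#' order-of-magnitude plausible cephalometric scales (ANB near 0 degrees
#' for a Class III imbalance, IMPA near 87 degrees, PPPM near 28 degrees,
#' CoA near 85 mm, GoPg near 72 mm, CoGo near 55 mm; these baselines are
#' arbitrary conventions, only the differences carry the signal).
#'
#' @param n_patients Number of patients.
#' @param treated_fraction Probability of a patient being treated.
#' @param truth Ground-truth `"gbn_fit"`; defaults to `make_truth(seed)`.
#' @param growth_link How the binary prognosis is drawn: `"logistic"`
#'   (realistic, via the truth's `growth_rule`) or `"threshold"` (the
#'   truth's Gaussian local model thresholded at 0.5, keeping the
#'   generative law exactly linear-Gaussian given the realised parents —
#'   the clean mode used by recovery studies).
#' @param blank_growth_treated Blank the prognosis of treated patients,
#'   matching a reporting convention where the prognosis is recorded for
#'   untreated subjects only. Off by default: the complete-data cohort is
#'   what a complete-data structure learner consumes, and with blanked
#'   treated prognoses the data cannot jointly identify `Treatment` and
#'   `Growth` effects (every complete row is untreated).
#' @param baseline Data frame (`feature`, `mean`, `sd`) of first-visit
#'   baselines.
#' @param age_t1_mean,age_t1_sd,age_t1_range First-visit age distribution.
#' @param dT_range Between-visit gap (uniform bounds, years).
#' @param seed Integer seed.
#' @return A `"generator_config"` list.
#' @export
generator_config <- function(n_patients = 143L,
                             treated_fraction = 66 / 143,
                             truth = NULL,
                             growth_link = c("logistic", "threshold"),
                             blank_growth_treated = FALSE,
                             baseline = NULL,
                             age_t1_mean = 8, age_t1_sd = 1,
                             age_t1_range = c(6, 19),
                             dT_range = c(4, 9),
                             seed = 1L) {
  growth_link <- match.arg(growth_link)
  stopifnot(n_patients >= 1L, treated_fraction >= 0, treated_fraction <= 1)
  if (is.null(truth)) truth <- make_truth(seed)
  stopifnot(inherits(truth, "gbn_fit"),
            setequal(truth$dag$nodes, .rate_nodes()))
  if (is.null(baseline)) {
    baseline <- data.frame(
      feature = ceph_features(),
      mean = c(-1, 87, 28, 85, 72, 55),
      sd = c(2, 6, 5, 4, 5, 5)
    )
  }
  stopifnot(setequal(baseline$feature, ceph_features()))
  structure(list(n_patients = as.integer(n_patients),
                 treated_fraction = treated_fraction, truth = truth,
                 growth_link = growth_link,
                 blank_growth_treated = blank_growth_treated,
                 baseline = baseline, age_t1_mean = age_t1_mean,
                 age_t1_sd = age_t1_sd, age_t1_range = age_t1_range,
                 dT_range = dT_range, seed = as.integer(seed)),
            class = "generator_config")
}

#' Simulate a two-visit cohort from a known ground truth
#'
#' Per patient: draws the treatment flag (Bernoulli), the first-visit age
#' (truncated normal) and the between-visit gap (uniform); draws the six
#' craniofacial differences and the binary prognosis from the ground-truth
#' network by forward sampling in topological order, with `dT` and
#' `Treatment` forced to the drawn values and `Growth` drawn per the
#' configured link; draws the first-visit values from the baseline
#' distributions and sets the second visit to baseline plus difference.
#'
#' @param config A [generator_config()].
#' @return A validated `"ceph_cohort"`; [compute_differences()] on it
#'   reproduces the simulated differences exactly.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_patients
  truth <- config$truth
  nodes <- truth$dag$nodes

  treatment <- stats::rbinom(n, 1L, config$treated_fraction)
  dT <- stats::runif(n, config$dT_range[1L], config$dT_range[2L])
  lo <- stats::pnorm(config$age_t1_range[1L], config$age_t1_mean,
                     config$age_t1_sd)
  hi <- stats::pnorm(config$age_t1_range[2L], config$age_t1_mean,
                     config$age_t1_sd)
  age_t1 <- stats::qnorm(stats::runif(n, lo, hi), config$age_t1_mean,
                         config$age_t1_sd)

  X <- matrix(NA_real_, n, length(nodes), dimnames = list(NULL, nodes))
  X[, "dT"] <- dT
  X[, "Treatment"] <- treatment
  for (i in .topo_order(truth$dag$amat)) {
    node <- nodes[i]
    if (node %in% c("dT", "Treatment")) next
    lm <- truth$locals[[node]]
    mu <- lm$intercept
    if (length(lm$parents) > 0L) {
      mu <- mu + drop(X[, lm$parents, drop = FALSE] %*% lm$coefficients)
    }
    if (node == "Growth") {
      if (config$growth_link == "logistic") {
        gamma <- attr(truth, "growth_rule")
        if (is.null(gamma)) {
          stop("truth lacks a growth_rule; use growth_link = \"threshold\"",
               call. = FALSE)
        }
        p <- stats::plogis(gamma["intercept"] + gamma["dT"] * dT +
                             gamma["Treatment"] * treatment)
        X[, i] <- stats::rbinom(n, 1L, p)
      } else {
        X[, i] <- as.numeric(stats::rnorm(n, mu, lm$residual_sd) >= 0.5)
      }
    } else {
      X[, i] <- stats::rnorm(n, mu, lm$residual_sd)
    }
  }

  df <- data.frame(id = sprintf("P%03d", seq_len(n)),
                   treated = treatment,
                   growth = X[, "Growth"],
                   age_t1 = age_t1, age_t2 = age_t1 + dT)
  for (f in ceph_features()) {
    b <- config$baseline[config$baseline$feature == f, ]
    t1 <- stats::rnorm(n, b$mean, b$sd)
    df[[paste0(f, "_t1")]] <- t1
    df[[paste0(f, "_t2")]] <- t1 + X[, paste0("d", f)]
  }
  if (config$blank_growth_treated) df$growth[df$treated == 1] <- NA_real_
  out <- new_cohort(df, provenance = "raw")
  validate_cohort(out)
  out
}

#' Forward-sample a rate table directly from a truth network
#'
#' Convenience for simulation studies that need the node-ready difference
#' table without the cohort wrapper: forward samples from the network and
#' thresholds the binary nodes at 0.5.
#'
#' @param truth A `"gbn_fit"`.
#' @param n Number of rows.
#' @param seed Optional integer seed.
#' @return A data frame with the truth's nodes as columns.
#' @export
simulate_rate_table <- function(truth, n, seed = NULL) {
  stopifnot(inherits(truth, "gbn_fit"))
  raw <- logic_sample(truth, n, seed = seed)
  .threshold_binary(raw, truth$binary_nodes)
}
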