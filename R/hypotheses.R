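# Scripted clinical hypothesis queries: simulated-regression slopes,
# treated/untreated prognosis probabilities with and without interventions,
# and treated/untreated subgroup consensus networks. Every computation is a
# thin composition of inference-engine calls so the hypothesis logic stays
# auditable, and every output carries a Monte-Carlo standard error.

#' Simulated-regression slope between two nodes
#'
#' Draws `n` forward samples from the network and regresses `y` on `x` by
#' ordinary least squares, returning the slope, its sign and its standard
#' error. This mirrors the simulated-values regression used to check
#' qualitative clinical claims such as "an excessive ramus growth reduces
#' the palatal-mandibular angle" (negative `dCoGo -> dPPPM` slope) or "the
#' maxillomandibular imbalance moves with the incisor inclination"
#' (positive `dIMPA`/`dANB` slope).
#'
#' @param fit A `"gbn_fit"`.
#' @param x,y Regressor and response node names.
#' @param n Number of simulated draws.
#' @param seed Optional integer seed.
#' @return List with `slope`, `sign`, `se`, `n`.
#' @export
slope_query <- function(fit, x, y, n = 1e4, seed = NULL) {
  stopifnot(inherits(fit, "gbn_fit"))
  if (!all(c(x, y) %in% fit$dag$nodes)) {
    stop("unknown node(s): ",
         paste(setdiff(c(x, y), fit$dag$nodes), collapse = ", "),
         call. = FALSE)
  }
  sim <- logic_sample(fit, n, seed = seed)
  xv <- sim[[x]]
  yv <- sim[[y]]
  if (stats::var(xv) <= 100 * SD_FLOOR^2) {
    stop("regressor ", x, " has (near-)zero variance in the simulation",
         call. = FALSE)
  }
  f <- stats::lm(yv ~ xv)
  slope <- unname(stats::coef(f)[2L])
  se <- unname(summary(f)$coefficients[2L, 2L])
  list(slope = slope, sign = sign(slope), se = se, n = n)
}

#' Prognosis probability for treated and untreated patients
#'
#' Estimates `P(Growth = 1 | Treatment = 1)` and
#' `P(Growth = 1 | Treatment = 0)` by logic sampling, optionally after a
#' do-style intervention ([intervene_fix()]) — e.g. clamping `dANB` at 0 to
#' emulate a treatment that stops the progression of the sagittal
#' imbalance.
#'
#' @param fit A `"gbn_fit"` containing `Growth` and `Treatment` nodes.
#' @param intervention Optional `list(node =, value =)` applied before
#'   querying.
#' @param n Samples per query.
#' @param seed Optional integer seed.
#' @return List with `treated` and `untreated`, each a `"gbn_query"`, plus
#'   `difference` and `combined_se` for their contrast.
#' @export
prognosis_query <- function(fit, intervention = NULL, n = 1e4, seed = NULL) {
  stopifnot(inherits(fit, "gbn_fit"))
  if (!all(c("Growth", "Treatment") %in% fit$dag$nodes)) {
    stop("network must contain Growth and Treatment nodes", call. = FALSE)
  }
  if (!is.null(intervention)) {
    fit <- intervene_fix(fit, intervention$node, intervention$value)
  }
  seed2 <- if (is.null(seed)) NULL else as.integer(seed) + 1L
  treated <- conditional_query(fit, event = list(Growth = 1),
                               evidence = list(Treatment = 1),
                               n = n, seed = seed)
  untreated <- conditional_query(fit, event = list(Growth = 1),
                                 evidence = list(Treatment = 0),
                                 n = n, seed = seed2)
  diff <- treated$estimate - untreated$estimate
  comb <- sqrt(treated$mc_se^2 + untreated$mc_se^2)
  list(treated = treated, untreated = untreated,
       difference = diff, combined_se = comb)
}

#' Treated/untreated subgroup consensus networks
#'
#' Splits the rows by `Treatment`, drops the (now constant) `Treatment`
#' column within each subgroup, and runs the full bootstrap-consensus
#' pipeline separately on each, so the dependency structure of treated and
#' untreated patients can be compared.
#'
#' @param table Rate table containing a 0/1 `Treatment` column.
#' @param constraints A `"gbn_constraints"` for the full node set, or
#'   `NULL` for the tier defaults; arcs mentioning `Treatment` are removed
#'   for the subgroup runs.
#' @param R Bootstrap replicates per subgroup.
#' @param seed Integer seed (the untreated run uses `seed + 1`).
#' @param threshold Fixed inclusion threshold, or `NULL` to estimate per
#'   subgroup.
#' @param min_rows Minimal subgroup size (default 20).
#' @return List with elements `treated` and `untreated`, each a consensus
#'   `"gbn_dag"` (strengths in the `strengths` attribute).
#' @export
subgroup_networks <- function(table, constraints = NULL, R = 200L,
                              seed = NULL, threshold = NULL,
                              min_rows = 20L) {
  table <- as.data.frame(table)
  if (!"Treatment" %in% colnames(table)) {
    stop("table must contain a Treatment column", call. = FALSE)
  }
  n_tr <- sum(table$Treatment == 1)
  n_un <- sum(table$Treatment == 0)
  if (n_tr < min_rows || n_un < min_rows) {
    stop("subgroup too small: ", n_tr, " treated, ", n_un,
         " untreated rows (need >= ", min_rows, " each)", call. = FALSE)
  }
  sub_nodes <- setdiff(colnames(table), "Treatment")
  if (is.null(constraints)) {
    cons <- malocclusion_constraints(sub_nodes)
  } else {
    strip <- function(m) m[m[, 1L] != "Treatment" & m[, 2L] != "Treatment",
                           , drop = FALSE]
    cons <- constraints(whitelist = strip(constraints$whitelist),
                        blacklist = strip(constraints$blacklist))
  }
  run <- function(rows, s) {
    averaged_network(table[rows, sub_nodes, drop = FALSE], cons, R = R,
                     seed = s, threshold = threshold)
  }
  seed2 <- if (is.null(seed)) NULL else as.integer(seed) + 1L
  list(treated = run(table$Treatment == 1, seed),
       untreated = run(table$Treatment == 0, seed2))
}

#' Consolidated clinical hypothesis report
#'
#' Runs the four standard checks against a fitted network of the nine
#' rate-of-change variables:
#'
#' 1. slope of `dPPPM` on `dCoGo` in simulated values (expected negative:
#'    faster ramus growth closes the palatal-mandibular angle);
#' 2. slope of `dANB` on `dIMPA` (expected positive: the sagittal imbalance
#'    and the incisor compensation move together);
#' 3. prognosis probabilities for treated vs untreated patients, before and
#'    after clamping `dANB` at 0 (does a favourable prognosis reduce to
#'    stopping the progression of the imbalance?);
#' 4. mean `dANB` for treated vs untreated patients with `dGoPg` clamped at
#'    0 (mandibular body used as a proxy to control the position of point
#'    B).
#'
#' @param fit A `"gbn_fit"` over the standard node set.
#' @param n Samples per query.
#' @param seed Optional integer seed.
#' @return A `"hypothesis_report"` list with elements `h1`-`h4`.
#' @export
hypothesis_report <- function(fit, n = 1e4, seed = NULL) {
  stopifnot(inherits(fit, "gbn_fit"))
  s <- function(k) if (is.null(seed)) NULL else as.integer(seed) + k
  h1 <- slope_query(fit, x = "dCoGo", y = "dPPPM", n = n, seed = s(0L))
  h2 <- slope_query(fit, x = "dIMPA", y = "dANB", n = n, seed = s(10L))
  h3 <- list(
    observational = prognosis_query(fit, n = n, seed = s(20L)),
    anb_fixed = prognosis_query(fit,
                                intervention = list(node = "dANB", value = 0),
                                n = n, seed = s(30L))
  )
  fit4 <- intervene_fix(fit, "dGoPg", 0)
  h4 <- list(
    treated = conditional_query(fit4, event = "dANB",
                                evidence = list(Treatment = 1),
                                n = n, seed = s(40L)),
    untreated = conditional_query(fit4, event = "dANB",
                                  evidence = list(Treatment = 0),
                                  n = n, seed = s(50L))
  )
  structure(list(h1 = h1, h2 = h2, h3 = h3, h4 = h4, n = n),
            class = "hypothesis_report")
}

#' @export
print.hypothesis_report <- function(x, ...) {
  cat("Clinical hypothesis report (", x$n, " samples per query)\n", sep = "")
  cat(sprintf("  1. slope dPPPM ~ dCoGo: %.3f (se %.3g) -> %s\n",
              x$h1$slope, x$h1$se,
              if (x$h1$sign < 0) "negative, ramus growth closes PP-MP"
              else "non-negative"))
  cat(sprintf("  2. slope dANB ~ dIMPA: %.3f (se %.3g) -> %s\n",
              x$h2$slope, x$h2$se,
              if (x$h2$sign > 0) "positive, imbalance tracks compensation"
              else "non-positive"))
  o <- x$h3$observational
  i <- x$h3$anb_fixed
  cat(sprintf("  3. P(good grower): treated %.3f vs untreated %.3f;\n",
              o$treated$estimate, o$untreated$estimate))
  cat(sprintf("     with dANB fixed at 0: %.3f vs %.3f (combined se %.3g)\n",
              i$treated$estimate, i$untreated$estimate, i$combined_se))
  cat(sprintf("  4. mean dANB with dGoPg fixed at 0: treated %+.3f, untreated %+.3f\n",
              x$h4$treated$estimate, x$h4$untreated$estimate))
  invisible(x)
}

#' Write a hypothesis report as JSON
#'
#' @param report A `"hypothesis_report"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hypothesis_report <- function(report, path) {
  stopifnot(inherits(report, "hypothesis_report"))
  q <- function(z) list(estimate = z$estimate, mc_se = z$mc_se,
                        n_matched_evidence = z$n_matched_evidence)
  jsonlite::write_json(list(
    h1_slope_dPPPM_on_dCoGo = report$h1[c("slope", "se")],
    h2_slope_dANB_on_dIMPA = report$h2[c("slope", "se")],
    h3_prognosis = list(
      observational = list(treated = q(report$h3$observational$treated),
                           untreated = q(report$h3$observational$untreated)),
      anb_fixed = list(treated = q(report$h3$anb_fixed$treated),
                       untreated = q(report$h3$anb_fixed$untreated))
    ),
    h4_dANB_with_dGoPg_fixed = list(treated = q(report$h4$treated),
                                    untreated = q(report$h4$untreated))
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
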