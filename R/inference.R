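# Forward (logic) sampling, rejection-based conditional probability
# queries, the exact multivariate-normal oracle implied by a fitted
# network, and do-style interventions by graph mutilation.

#' Forward (logic) sampling from a fitted network
#'
#' Generates `n` joint draws by visiting nodes in topological order and
#' drawing each from the normal distribution implied by its local model,
#' `N(intercept + sum(beta * parent values), residual_sd^2)`.
#'
#' @param fit A `"gbn_fit"`.
#' @param n Number of samples (`>= 1`).
#' @param seed Optional integer seed; the same seed reproduces the table
#'   exactly.
#' @return A data frame of `n` rows, one column per node, with the fit's
#'   `binary_nodes` recorded in the attribute of the same name.
#' @export
logic_sample <- function(fit, n, seed = NULL) {
  stopifnot(inherits(fit, "gbn_fit"), n >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  nodes <- fit$dag$nodes
  ord <- .topo_order(fit$dag$amat)
  X <- matrix(NA_real_, nrow = n, ncol = length(nodes),
              dimnames = list(NULL, nodes))
  for (i in ord) {
    lm <- fit$locals[[nodes[i]]]
    mu <- lm$intercept
    if (length(lm$parents) > 0L) {
      mu <- mu + drop(X[, lm$parents, drop = FALSE] %*% lm$coefficients)
    }
    X[, i] <- stats::rnorm(n, mean = mu, sd = lm$residual_sd)
  }
  out <- as.data.frame(X)
  attr(out, "binary_nodes") <- fit$binary_nodes
  out
}

# 0/1 view of the binary nodes (thresholded at 0.5); other columns
# untouched.
.threshold_binary <- function(samples, binary_nodes) {
  for (b in intersect(binary_nodes, names(samples))) {
    samples[[b]] <- as.numeric(samples[[b]] >= 0.5)
  }
  samples
}

#' Interval evidence helper
#'
#' Turns a point value into the interval `[x - halfwidth, x + halfwidth]`
#' for use as evidence or event on a continuous node: point evidence has
#' probability zero under forward sampling, so "approximately x" is
#' expressed as a narrow interval (default half-width 0.1 units).
#'
#' @param x Centre value.
#' @param halfwidth Half-width of the interval.
#' @return A length-2 numeric interval.
#' @export
near <- function(x, halfwidth = 0.1) c(x - halfwidth, x + halfwidth)

# Logical match of a predicate (named list of intervals / binary values)
# against sampled rows; binary nodes are compared on their thresholded 0/1
# view.
.match_predicate <- function(raw, thresholded, predicate, binary_nodes) {
  ok <- rep(TRUE, nrow(raw))
  if (is.null(predicate) || length(predicate) == 0L) return(ok)
  if (is.null(names(predicate)) || any(names(predicate) == "")) {
    stop("predicates must be named lists (node = interval or value)",
         call. = FALSE)
  }
  for (node in names(predicate)) {
    if (!node %in% names(raw)) {
      stop("predicate references unknown node: ", node, call. = FALSE)
    }
    spec <- predicate[[node]]
    binary <- node %in% binary_nodes
    col <- if (binary) thresholded[[node]] else raw[[node]]
    if (length(spec) == 2L) {
      ok <- ok & col >= spec[1L] & col <= spec[2L]
    } else if (length(spec) == 1L) {
      if (!binary) {
        stop("point condition on continuous node ", node,
             " has probability zero under forward sampling; use an ",
             "interval, e.g. near(", spec, ")", call. = FALSE)
      }
      ok <- ok & col == spec
    } else {
      stop("condition on ", node, " must be a value or a length-2 interval",
           call. = FALSE)
    }
  }
  ok
}

#' Conditional probability query by logic sampling
#'
#' Estimates `P(event | evidence)` by rejection: forward-samples the
#' network, keeps the draws matching the evidence, and returns the fraction
#' also matching the event together with the binomial Monte-Carlo standard
#' error `sqrt(p(1-p)/n_E)`. When `event` is a node name instead of a
#' predicate, the posterior mean of that node over the evidence-matching
#' draws is returned (a parameter query), with the standard error of the
#' mean.
#'
#' Events and evidence are named lists of conditions, conjunctively
#' combined: a length-2 numeric interval for continuous nodes (see
#' [near()]), or a 0/1 value for binary nodes, which are evaluated on
#' their thresholded (at 0.5) sampled values.
#'
#' @param fit A `"gbn_fit"`.
#' @param event Predicate list, or a single node name for a parameter
#'   query.
#' @param evidence Predicate list, or `NULL` for an unconditional query.
#' @param n Number of forward samples (default `1e4`, the customary range
#'   being `1e4`-`1e6`).
#' @param seed Optional integer seed.
#' @return A `"gbn_query"`: `estimate`, `mc_se`, `n_matched_evidence`,
#'   `n_samples`, `type` (`"probability"` or `"mean"`) and `matched`
#'   (`FALSE` when no draw satisfied the evidence, in which case the
#'   estimate is `NA` rather than a number).
#' @examples
#' net <- gbn_network(list(
#'   x = list(intercept = 0, coefficients = numeric(0), residual_sd = 1)
#' ))
#' conditional_query(net, event = list(x = c(0, Inf)), n = 1e4, seed = 1)
#' @export
conditional_query <- function(fit, event, evidence = NULL, n = 1e4,
                              seed = NULL) {
  stopifnot(inherits(fit, "gbn_fit"), n >= 1L)
  raw <- logic_sample(fit, n, seed = seed)
  thr <- .threshold_binary(raw, fit$binary_nodes)
  ev <- .match_predicate(raw, thr, evidence, fit$binary_nodes)
  n_E <- sum(ev)
  if (n_E == 0L) {
    return(structure(list(estimate = NA_real_, mc_se = NA_real_,
                          n_matched_evidence = 0L, n_samples = n,
                          type = "probability", matched = FALSE),
                     class = "gbn_query"))
  }
  if (is.character(event) && length(event) == 1L) {
    if (!event %in% names(raw)) {
      stop("unknown node in parameter query: ", event, call. = FALSE)
    }
    vals <- raw[[event]][ev]
    est <- mean(vals)
    se <- stats::sd(vals) / sqrt(n_E)
    type <- "mean"
  } else {
    q <- .match_predicate(raw, thr, event, fit$binary_nodes)
    est <- sum(q & ev) / n_E
    se <- sqrt(est * (1 - est) / n_E)
    type <- "probability"
  }
  structure(list(estimate = est, mc_se = se,
                 n_matched_evidence = as.integer(n_E), n_samples = n,
                 type = type, matched = TRUE),
            class = "gbn_query")
}

#' @export
print.gbn_query <- function(x, ...) {
  if (!x$matched) {
    cat("No sampled draw matched the evidence (n =", x$n_samples, ")\n")
  } else {
    cat(sprintf("%s = %.4g (MC se %.3g, n_E = %d of %d)\n",
                if (x$type == "mean") "posterior mean" else "estimate",
                x$estimate, x$mc_se, x$n_matched_evidence, x$n_samples))
  }
  invisible(x)
}

#' Implied joint Gaussian distribution of a fitted network
#'
#' Resolves the recursive linear-Gaussian system into its joint
#' multivariate normal: with coefficient matrix `B` (`B[parent, child]`),
#' intercepts `a` and residual variances `D`, the joint is
#' `N((I - B')^{-1} a, (I - B')^{-1} D (I - B')^{-T})`.
#'
#' @param fit A `"gbn_fit"`.
#' @return A `"gbn_mvn"`: list with `nodes`, `mean`, `cov`.
#' @export
implied_moments <- function(fit) {
  stopifnot(inherits(fit, "gbn_fit"))
  nodes <- fit$dag$nodes
  N <- length(nodes)
  B <- matrix(0, N, N, dimnames = list(nodes, nodes))
  a <- numeric(N)
  d <- numeric(N)
  for (i in seq_len(N)) {
    lm <- fit$locals[[nodes[i]]]
    if (length(lm$parents) > 0L) B[lm$parents, i] <- lm$coefficients
    a[i] <- lm$intercept
    d[i] <- lm$residual_sd^2
  }
  M <- solve(diag(N) - t(B))
  mean <- drop(M %*% a)
  cov <- M %*% diag(d, N) %*% t(M)
  dimnames(cov) <- list(nodes, nodes)
  structure(list(nodes = nodes, mean = stats::setNames(mean, nodes),
                 cov = cov),
            class = "gbn_mvn")
}

# Solves S x = B for symmetric PSD S. Cholesky when well conditioned,
# eigen-pseudoinverse otherwise: near-deterministic local models (residual
# sds at the floor) make implied covariances singular at floating
# precision, and the pseudoinverse gives the correct conditional-mean
# limit there.
.solve_psd <- function(S, B) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(R)) {
    d <- diag(R)
    if (min(d) > sqrt(.Machine$double.eps) * max(d)) {
      return(backsolve(R, forwardsolve(t(R), B)))
    }
  }
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * .Machine$double.eps * length(e$values)
  if (!any(keep)) stop("singular covariance; cannot condition",
                       call. = FALSE)
  V <- e$vectors[, keep, drop = FALSE]
  V %*% ((t(V) %*% B) / e$values[keep])
}

#' Exact Gaussian conditioning on point evidence
#'
#' Computes the implied joint normal of the network (see
#' [implied_moments()]) and conditions it exactly on point values for a
#' subset of nodes, returning the conditional mean vector and covariance
#' matrix of the remaining nodes. This is the closed-form oracle the logic
#' sampler is validated against, and the deterministic predictor used by
#' [cross_validate()].
#'
#' @param fit A `"gbn_fit"`.
#' @param evidence Named numeric vector/list of observed node values; empty
#'   or `NULL` returns the implied marginals unchanged.
#' @return A `"gbn_mvn"` over the non-evidence nodes.
#' @export
exact_conditional <- function(fit, evidence = NULL) {
  mom <- implied_moments(fit)
  if (is.null(evidence) || length(evidence) == 0L) return(mom)
  evidence <- unlist(evidence)
  e <- names(evidence)
  if (is.null(e) || !all(e %in% mom$nodes)) {
    stop("evidence must be named with existing nodes", call. = FALSE)
  }
  if (anyNA(evidence) || any(!is.finite(evidence))) {
    stop("evidence values must be finite", call. = FALSE)
  }
  u <- setdiff(mom$nodes, e)
  S_ee <- mom$cov[e, e, drop = FALSE]
  w <- .solve_psd(S_ee, evidence - mom$mean[e])
  if (length(u) == 0L) {
    return(structure(list(nodes = character(0), mean = numeric(0),
                          cov = matrix(0, 0, 0)), class = "gbn_mvn"))
  }
  S_ue <- mom$cov[u, e, drop = FALSE]
  K <- .solve_psd(S_ee, t(S_ue))
  mean_u <- mom$mean[u] + drop(S_ue %*% w)
  cov_u <- mom$cov[u, u, drop = FALSE] - S_ue %*% K
  structure(list(nodes = u, mean = mean_u, cov = cov_u), class = "gbn_mvn")
}

#' @export
print.gbn_mvn <- function(x, ...) {
  cat("Gaussian distribution over", length(x$nodes), "node(s)\n")
  if (length(x$nodes) > 0L) {
    print(data.frame(node = x$nodes, mean = unname(x$mean),
                     sd = sqrt(pmax(diag(x$cov), 0))), row.names = FALSE)
  }
  invisible(x)
}

#' Exact probability of a one-node event given one-node interval evidence
#'
#' Closed-form/quadrature counterpart of [conditional_query()] for the
#' common single-node case: `P(event_node in event_range | evidence_node in
#' evidence_range)` under the implied joint normal. With no evidence this
#' is a marginal normal probability; with interval evidence the conditional
#' event probability is integrated over the evidence node's truncated
#' marginal with [stats::integrate()].
#'
#' Note that binary nodes are treated on their underlying Gaussian scale
#' here; an event `Growth = 1` corresponds to the interval `[0.5, Inf)`.
#'
#' @param fit A `"gbn_fit"`.
#' @param event_node,event_range Queried node and its length-2 interval.
#' @param evidence_node,evidence_range Optional conditioning node and its
#'   length-2 interval.
#' @return The exact probability.
#' @export
exact_query <- function(fit, event_node, event_range,
                        evidence_node = NULL, evidence_range = NULL) {
  mom <- implied_moments(fit)
  stopifnot(event_node %in% mom$nodes, length(event_range) == 2L)
  mq <- mom$mean[event_node]
  sq2 <- mom$cov[event_node, event_node]
  if (is.null(evidence_node)) {
    s <- sqrt(sq2)
    return(stats::pnorm(event_range[2L], mq, s) -
             stats::pnorm(event_range[1L], mq, s))
  }
  stopifnot(evidence_node %in% mom$nodes, length(evidence_range) == 2L,
            evidence_node != event_node)
  me <- mom$mean[evidence_node]
  se2 <- mom$cov[evidence_node, evidence_node]
  cqe <- mom$cov[event_node, evidence_node]
  cond_sd <- sqrt(max(sq2 - cqe^2 / se2, 0))
  se <- sqrt(se2)
  f <- function(x) {
    m <- mq + cqe / se2 * (x - me)
    stats::dnorm(x, me, se) *
      (stats::pnorm(event_range[2L], m, cond_sd) -
         stats::pnorm(event_range[1L], m, cond_sd))
  }
  num <- stats::integrate(f, evidence_range[1L], evidence_range[2L],
                          rel.tol = 1e-9)$value
  den <- stats::pnorm(evidence_range[2L], me, se) -
    stats::pnorm(evidence_range[1L], me, se)
  if (den <= 0) stop("evidence interval has probability zero", call. = FALSE)
  num / den
}

#' Do-style intervention: fix a node at a value
#'
#' Mutilates the network in the sense of the do-operator: all arcs into
#' `node` are removed (making it independent of its former parents) and its
#' local model is replaced by the constant `value` with residual standard
#' deviation at the floor. All other local models are untouched, so
#' downstream effects of the fixed value still propagate.
#'
#' The operation is idempotent and commutes across interventions on
#' distinct nodes.
#'
#' @param fit A `"gbn_fit"`.
#' @param node Node to fix.
#' @param value Value to clamp it at.
#' @param sd_floor Residual standard deviation given to the fixed node.
#' @return The mutilated `"gbn_fit"`; applied interventions are recorded in
#'   the `interventions` element.
#' @export
intervene_fix <- function(fit, node, value, sd_floor = SD_FLOOR) {
  stopifnot(inherits(fit, "gbn_fit"))
  if (!node %in% fit$dag$nodes) stop("unknown node: ", node, call. = FALSE)
  fit$dag$amat[, node] <- 0L
  fit$locals[[node]] <- list(node = node, parents = character(0),
                             intercept = as.numeric(value),
                             coefficients = numeric(0),
                             residual_sd = sd_floor)
  fit$interventions <- unique(rbind(fit$interventions,
                                    data.frame(node = node, value = value)))
  fit
}
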