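# BIC scoring of linear-Gaussian local models. All regressions are solved
# from cross-product matrices so that a single O(n p^2) pass per dataset
# supports the thousands of local scores evaluated during hill-climbing and
# bootstrap averaging; each score then costs one small Cholesky solve.

# Default lower bound on residual standard deviations. Guards logic sampling
# and log-likelihoods against degenerate (interpolating) fits.
SD_FLOOR <- 1e-6

# Precomputes cross-product matrices for a numeric data frame. Columns with
# missing values (in practice only Growth) get a complete-case companion
# matrix; local models whose scope touches them are fitted listwise on it.
.score_context <- function(data) {
  X <- as.matrix(as.data.frame(data))
  if (!is.numeric(X)) stop("all columns must be numeric", call. = FALSE)
  nodes <- colnames(X)
  if (is.null(nodes) || anyDuplicated(nodes)) {
    stop("data must have unique column names", call. = FALSE)
  }
  na_vars <- nodes[colSums(is.na(X)) > 0L]
  X0 <- X
  X0[is.na(X0)] <- 0
  C_all <- crossprod(cbind(`(Intercept)` = 1, X0))
  cc <- stats::complete.cases(X)
  if (length(na_vars) > 0L) {
    C_cc <- crossprod(cbind(`(Intercept)` = 1, X[cc, , drop = FALSE]))
  } else {
    C_cc <- C_all
  }
  list(nodes = nodes, na_vars = na_vars,
       C_all = C_all, n_all = nrow(X),
       C_cc = C_cc, n_cc = sum(cc))
}

# Least squares of `node` on `parents` from a cross-product matrix.
# Returns NULL when the design is singular.
.ols_from_C <- function(C, node, parents) {
  idx <- c("(Intercept)", parents)
  M <- C[idx, idx, drop = FALSE]
  v <- C[idx, node]
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  d <- diag(R)
  if (min(d) < sqrt(.Machine$double.eps) * max(d)) return(NULL)
  b <- backsolve(R, forwardsolve(t(R), v))
  rss <- max(C[node, node] - sum(v * b), 0)
  list(coef = stats::setNames(b, idx), rss = rss)
}

# Local BIC on the log-likelihood scale. Returns a list so callers can tell
# singular designs (-Inf, singular = TRUE) and variance clamping apart.
.local_score <- function(ctx, node, parents, sd_floor = SD_FLOOR) {
  affected <- c(node, parents) %in% ctx$na_vars
  if (any(affected)) {
    C <- ctx$C_cc
    n <- ctx$n_cc
  } else {
    C <- ctx$C_all
    n <- ctx$n_all
  }
  k <- length(parents) + 2
  if (n < length(parents) + 2L) {
    stop("too few rows (", n, ") to score ", node, " on ",
         length(parents), " parent(s)", call. = FALSE)
  }
  fit <- .ols_from_C(C, node, parents)
  if (is.null(fit)) {
    return(list(score = -Inf, singular = TRUE, clamped = FALSE))
  }
  sigma2 <- fit$rss / n
  clamped <- sigma2 < sd_floor^2
  if (clamped) sigma2 <- sd_floor^2
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  list(score = loglik - k / 2 * log(n), singular = FALSE, clamped = clamped)
}

#' Local BIC score of one node given a parent set
#'
#' Scores the linear-Gaussian local model of `node` regressed on `parents`
#' as the maximised Gaussian log-likelihood minus `(k/2) log(n)`, with
#' `k = |parents| + 2` free parameters (intercept, slopes, residual
#' variance). Residual variance uses the maximum-likelihood `n` denominator.
#' Higher is better, and the score of a whole network decomposes as the sum
#' of its local scores (see [score_network()]).
#'
#' Rows with missing values in any variable of the local model's scope are
#' dropped listwise for that score only.
#'
#' @param node Column name of the response variable.
#' @param parents Character vector of parent column names (may be empty).
#' @param data Numeric data frame (e.g. a rate table from
#'   [compute_differences()]).
#' @param sd_floor Lower bound for the residual standard deviation; variances
#'   below `sd_floor^2` are clamped with a warning.
#' @return The local BIC score (a scalar; higher is better).
#' @examples
#' tab <- data.frame(x = rnorm(50), e = rnorm(50))
#' tab$y <- 2 * tab$x + 0.5 * tab$e
#' bic_local("y", "x", tab) > bic_local("y", character(0), tab)
#' @export
bic_local <- function(node, parents = character(0), data,
                      sd_floor = SD_FLOOR) {
  ctx <- .score_context(data)
  if (!node %in% ctx$nodes) stop("unknown node: ", node, call. = FALSE)
  parents <- as.character(parents)
  if (!all(parents %in% ctx$nodes)) {
    stop("unknown parent(s): ",
         paste(setdiff(parents, ctx$nodes), collapse = ", "), call. = FALSE)
  }
  if (node %in% parents) stop("node cannot be its own parent", call. = FALSE)
  res <- .local_score(ctx, node, parents, sd_floor)
  if (res$singular) {
    stop("singular design when scoring ", node, " on {",
         paste(parents, collapse = ", "), "}; collinear parents",
         call. = FALSE)
  }
  if (res$clamped) {
    warning("residual variance of ", node, " clamped at sd_floor^2",
            call. = FALSE)
  }
  res$score
}

#' Total BIC score of a network structure
#'
#' Sums [bic_local()] over all nodes of `x` with their parent sets in the
#' DAG; by decomposability this is the network score maximised by
#' [hill_climb()].
#'
#' @param x A `"gbn_dag"` object whose nodes are columns of `data`.
#' @inheritParams bic_local
#' @return The total score (scalar; higher is better).
#' @export
score_network <- function(x, data, sd_floor = SD_FLOOR) {
  stopifnot(inherits(x, "gbn_dag"))
  ctx <- .score_context(data)
  if (!all(x$nodes %in% ctx$nodes)) {
    stop("data lacks column(s): ",
         paste(setdiff(x$nodes, ctx$nodes), collapse = ", "), call. = FALSE)
  }
  total <- 0
  for (node in x$nodes) {
    res <- .local_score(ctx, node, parents(x, node), sd_floor)
    if (res$singular) {
      stop("singular design when scoring ", node, call. = FALSE)
    }
    total <- total + res$score
  }
  total
}

#' Enumerate all DAGs over a (small) node set
#'
#' Exhaustive generation of every directed acyclic graph over `nodes`, used
#' as the brute-force search oracle in the structure-learning validation
#' studies. Feasible up to 4-5 nodes (543 DAGs on 4 nodes, 29281 on 5).
#'
#' @param nodes Character vector of node names (at most 5).
#' @return A list of `"gbn_dag"` objects.
#' @export
enumerate_dags <- function(nodes) {
  N <- length(nodes)
  if (N > 5L) stop("enumeration supported for at most 5 nodes", call. = FALSE)
  pairs <- which(diag(N) == 0, arr.ind = TRUE) # ordered pairs, no self-loops
  m <- nrow(pairs)
  out <- vector("list", 0L)
  for (mask in 0:(2^m - 1)) {
    amat <- matrix(0L, N, N, dimnames = list(nodes, nodes))
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(sel) > 0L) amat[pairs[sel, , drop = FALSE]] <- 1L
    if (!is.null(.topo_order(amat))) out[[length(out) + 1L]] <- new_dag(nodes, amat)
  }
  out
}
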