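# Parameter learning: ordinary least squares for every local model of a
# linear-Gaussian network, plus constructors for hand-specified networks
# (used for ground truths and in tests).

new_gbn_fit <- function(dag, locals, sample_size,
                        binary_nodes = character(0)) {
  structure(list(dag = dag, locals = locals, sample_size = sample_size,
                 binary_nodes = binary_nodes),
            class = "gbn_fit")
}

#' Fit a linear-Gaussian Bayesian network by ordinary least squares
#'
#' Estimates, for every node of `x`, the local regression on its parents:
#' intercept and slopes by least squares, residual standard deviation from
#' the residual sum of squares with the maximum-likelihood `n` denominator
#' (matching [bic_local()]). Residual standard deviations are floored at
#' `sd_floor`.
#'
#' Rows with missing values are dropped listwise per local model, so a
#' missing prognosis only affects the models whose scope includes `Growth`.
#'
#' @param x A `"gbn_dag"` structure.
#' @param data Numeric data frame containing every node as a column.
#' @param sd_floor Lower bound for fitted residual standard deviations.
#' @param binary_nodes Names of 0/1-coded nodes (thresholded at 0.5 by the
#'   query engine); defaults to whichever of `Treatment`, `Growth` are
#'   present.
#' @return A `"gbn_fit"` object: the DAG, one local model per node
#'   (`parents`, `intercept`, `coefficients`, `residual_sd`) and the sample
#'   size used.
#' @examples
#' tab <- data.frame(x = rnorm(100))
#' tab$y <- 2 + 3 * tab$x + rnorm(100, sd = 0.3)
#' fit <- fit_ols(dag(c("x", "y"), c("x", "y")), tab)
#' fit$locals$y$coefficients
#' @export
fit_ols <- function(x, data, sd_floor = SD_FLOOR,
                    binary_nodes = intersect(c("Treatment", "Growth"),
                                             colnames(data))) {
  stopifnot(inherits(x, "gbn_dag"))
  ctx <- .score_context(data)
  if (!all(x$nodes %in% ctx$nodes)) {
    stop("data lacks column(s): ",
         paste(setdiff(x$nodes, ctx$nodes), collapse = ", "), call. = FALSE)
  }
  locals <- stats::setNames(vector("list", length(x$nodes)), x$nodes)
  for (node in x$nodes) {
    pa <- parents(x, node)
    affected <- any(c(node, pa) %in% ctx$na_vars)
    C <- if (affected) ctx$C_cc else ctx$C_all
    n <- if (affected) ctx$n_cc else ctx$n_all
    if (n < length(pa) + 2L) {
      stop("too few rows (", n, ") to fit ", node, " on ",
           length(pa), " parent(s)", call. = FALSE)
    }
    fit <- .ols_from_C(C, node, pa)
    if (is.null(fit)) {
      stop("singular design when fitting node ", node, call. = FALSE)
    }
    locals[[node]] <- list(
      node = node,
      parents = pa,
      intercept = unname(fit$coef["(Intercept)"]),
      coefficients = fit$coef[pa],
      residual_sd = max(sqrt(fit$rss / n), sd_floor)
    )
  }
  new_gbn_fit(x, locals, as.integer(ctx$n_all), binary_nodes)
}

#' Assemble a Gaussian Bayesian network from explicit local models
#'
#' Builds a `"gbn_fit"` directly from intercepts, parent coefficients and
#' residual standard deviations, e.g. to encode a known ground truth or a
#' textbook example.
#'
#' @param locals Named list, one entry per node, each a list with elements
#'   `coefficients` (named numeric vector over the parents; may be empty),
#'   `intercept` and `residual_sd`.
#' @param binary_nodes Names of 0/1-coded nodes (see [fit_ols()]).
#' @param nodes Optional node order; defaults to the order of `locals`.
#' @return A `"gbn_fit"` object.
#' @examples
#' net <- gbn_network(list(
#'   x = list(intercept = 0, coefficients = numeric(0), residual_sd = 1),
#'   y = list(intercept = 2, coefficients = c(x = 3), residual_sd = 1)
#' ))
#' @export
gbn_network <- function(locals, binary_nodes = character(0), nodes = NULL) {
  if (is.null(nodes)) nodes <- names(locals)
  stopifnot(!is.null(nodes), setequal(nodes, names(locals)))
  arcs <- NULL
  for (node in nodes) {
    lm <- locals[[node]]
    pa <- names(lm$coefficients)
    if (length(lm$coefficients) > 0L && is.null(pa)) {
      stop("coefficients of ", node, " must be named by parent", call. = FALSE)
    }
    if (length(pa) > 0L) arcs <- rbind(arcs, cbind(pa, node))
    if (!is.numeric(lm$intercept) || length(lm$intercept) != 1L ||
        !is.numeric(lm$residual_sd) || lm$residual_sd <= 0) {
      stop("node ", node, ": intercept must be scalar and residual_sd > 0",
           call. = FALSE)
    }
  }
  g <- dag(nodes, arcs)
  locals <- lapply(stats::setNames(nodes, nodes), function(node) {
    lm <- locals[[node]]
    pa <- names(lm$coefficients) %||% character(0)
    list(node = node, parents = pa,
         intercept = unname(lm$intercept),
         coefficients = stats::setNames(as.numeric(lm$coefficients), pa),
         residual_sd = unname(lm$residual_sd))
  })
  new_gbn_fit(g, locals, NA_integer_, binary_nodes)
}

#' @export
print.gbn_fit <- function(x, ...) {
  cat("Linear-Gaussian Bayesian network over", length(x$dag$nodes),
      "nodes,", nrow(arcs(x$dag)), "arcs")
  if (!is.na(x$sample_size)) cat(" (fitted on n =", x$sample_size, "rows)")
  cat("\n")
  for (lm in x$locals) {
    rhs <- if (length(lm$parents) == 0L) "1" else
      paste(sprintf("%+.3g*%s", lm$coefficients, lm$parents), collapse = " ")
    cat(sprintf("  %s ~ %.3g %s  (sd %.3g)\n", lm$node, lm$intercept,
                if (rhs == "1") "" else rhs, lm$residual_sd))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
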