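# Pairwise Pearson correlation matrix and the thresholded undirected
# correlation network — the descriptive baseline model the directed network
# analysis is compared against.

#' Pearson correlation coefficient
#'
#' Two-pass sample correlation: deviations from the mean, cross-products,
#' normalised by the root sums of squares. Kept as the single correlation
#' implementation used by both the correlation network and the predictive
#' correlation of [cross_validate()].
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return The correlation in `[-1, 1]`.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  ssx <- sum(dx^2)
  ssy <- sum(dy^2)
  if (ssx == 0 || ssy == 0) {
    stop("correlation undefined for a constant sequence", call. = FALSE)
  }
  sum(dx * dy) / (sqrt(ssx) * sqrt(ssy))
}

#' Thresholded Pearson correlation network
#'
#' Computes all pairwise Pearson correlations between the columns of a rate
#' table and links the pairs whose absolute correlation strictly exceeds
#' the threshold (default 0.4). The binary `Treatment` and `Growth` columns
#' participate on their 0/1 coding (point-biserial correlation equals
#' Pearson there). Pairs are computed on pairwise-complete rows, so a
#' missing prognosis drops rows only from the pairs involving `Growth`.
#'
#' @param table Numeric data frame (e.g. from [compute_differences()]) with
#'   at least 3 rows.
#' @param threshold Edge threshold on `|r|`, strict (`>`); boundary
#'   equality is excluded.
#' @return A `"ceph_cornet"`: list with `variables`, the correlation matrix
#'   `r_matrix` (unit diagonal; `NA` off-diagonal for constant columns,
#'   which are excluded from edges with a warning), the `edges` data frame
#'   (`var_a`, `var_b`, `r`) and `threshold`.
#' @export
correlation_network <- function(table, threshold = 0.4) {
  stopifnot(is.data.frame(table) || is.matrix(table))
  X <- as.matrix(as.data.frame(table))
  if (nrow(X) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  vars <- colnames(X)
  p <- length(vars)
  r <- diag(1, p)
  dimnames(r) <- list(vars, vars)
  constant <- logical(p)
  for (a in seq_len(p - 1L)) {
    for (b in (a + 1L):p) {
      ok <- stats::complete.cases(X[, c(a, b)])
      xa <- X[ok, a]
      xb <- X[ok, b]
      val <- if (sum(ok) < 3L || stats::var(xa) == 0 || stats::var(xb) == 0) {
        NA_real_
      } else {
        pearson_r(xa, xb)
      }
      r[a, b] <- r[b, a] <- val
    }
  }
  for (a in seq_len(p)) {
    xa <- X[!is.na(X[, a]), a]
    constant[a] <- length(xa) > 0L && stats::var(xa) == 0
  }
  if (any(constant)) {
    warning("constant column(s) excluded from edges: ",
            paste(vars[constant], collapse = ", "), call. = FALSE)
  }
  edges <- NULL
  for (a in seq_len(p - 1L)) {
    for (b in (a + 1L):p) {
      if (!is.na(r[a, b]) && abs(r[a, b]) > threshold) {
        edges <- rbind(edges, data.frame(var_a = vars[a], var_b = vars[b],
                                         r = r[a, b]))
      }
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(var_a = character(0), var_b = character(0),
                        r = numeric(0))
  }
  structure(list(variables = vars, r_matrix = r, edges = edges,
                 threshold = threshold),
            class = "ceph_cornet")
}

#' @export
print.ceph_cornet <- function(x, ...) {
  cat("Correlation network over", length(x$variables), "variables;",
      nrow(x$edges), "edges with |r| >", x$threshold, "\n")
  if (nrow(x$edges) > 0L) print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Export a correlation network
#'
#' `write_cornet_edges()` writes the edge list as TSV (`var_a`, `var_b`,
#' `r`); `write_cornet_matrix()` writes the full correlation matrix as CSV.
#'
#' @param network A `"ceph_cornet"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cornet_edges <- function(network, path) {
  stopifnot(inherits(network, "ceph_cornet"))
  utils::write.table(network$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_cornet_edges
#' @export
write_cornet_matrix <- function(network, path) {
  stopifnot(inherits(network, "ceph_cornet"))
  utils::write.csv(network$r_matrix, path, quote = FALSE)
  invisible(path)
}

#' Plot the correlation matrix as a heatmap
#'
#' Cosmetic convenience mirroring the usual correlation heatmap display;
#' requires no extra packages.
#'
#' @param x A `"ceph_cornet"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.ceph_cornet <- function(x, ...) {
  p <- length(x$variables)
  m <- x$r_matrix[, rev(seq_len(p))]
  m[is.na(m)] <- 0
  graphics::image(seq_len(p), seq_len(p), m, zlim = c(-1, 1),
                  col = grDevices::hcl.colors(51, "Blue-Red 3"),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(p), labels = x$variables, las = 2)
  graphics::axis(2, at = seq_len(p), labels = rev(x$variables), las = 2)
  invisible(x)
}
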