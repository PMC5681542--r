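# Bootstrap model averaging: arc strengths across resampled structure
# learns, a data-driven inclusion threshold, and consensus-DAG assembly.

new_strength_table <- function(df, replicates, nodes, failures = 0L) {
  structure(df, replicates = replicates, nodes = nodes,
            failures = failures,
            class = c("strength_table", "data.frame"))
}

#' Construct an arc-strength table
#'
#' Mostly used internally by [bootstrap_strengths()]; exposed so consensus
#' assembly can also be driven by externally computed (or hand-constructed)
#' strengths.
#'
#' @param df Data frame with columns `from`, `to` (the majority direction of
#'   each undirected pair), `strength` (frequency of the pair in `[0, 1]`)
#'   and `direction` (frequency of the majority direction given presence,
#'   in `[0, 1]`).
#' @param replicates Number of bootstrap replicates behind the frequencies.
#' @param nodes Node set of the underlying graphs; defaults to the nodes
#'   mentioned in `df`.
#' @return A `"strength_table"` data frame.
#' @export
strength_table <- function(df, replicates = NA_integer_, nodes = NULL) {
  needed <- c("from", "to", "strength", "direction")
  if (!all(needed %in% names(df))) {
    stop("strength table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$strength < 0 | df$strength > 1) ||
      any(df$direction < 0 | df$direction > 1)) {
    stop("strengths and directions must lie in [0, 1]", call. = FALSE)
  }
  pair <- paste(pmin(df$from, df$to), pmax(df$from, df$to))
  if (anyDuplicated(pair)) {
    stop("one row per undirected pair required", call. = FALSE)
  }
  if (is.null(nodes)) nodes <- sort(unique(c(df$from, df$to)))
  new_strength_table(df[order(df$from, df$to), , drop = FALSE],
                     as.integer(replicates), nodes)
}

#' Bootstrap arc strengths
#'
#' Draws `R` nonparametric bootstrap resamples of the rows (size `n`, with
#' replacement), learns a structure from each with [hill_climb()] under the
#' given constraints, and tabulates for every undirected pair of nodes the
#' *arc strength* (the fraction of replicate graphs containing the pair in
#' either direction) and the *direction strength* (the fraction, among
#' graphs containing it, orienting it the majority way). Whitelisted arcs
#' therefore have strength and direction 1 by construction; pairs
#' blacklisted in both directions have strength 0 and are omitted.
#'
#' Replicates on which learning fails are logged and excluded from the
#' denominator; the failure count is kept in the `failures` attribute.
#'
#' @param data Numeric data frame; columns are the network nodes.
#' @param constraints A `"gbn_constraints"` or `NULL`.
#' @param R Number of bootstrap replicates (200 by default).
#' @param seed Integer seed making the whole table bit-reproducible.
#' @param sd_floor Passed to [hill_climb()].
#' @return A `"strength_table"` with one row per pair observed at least
#'   once, majority direction in `(from, to)`.
#' @export
bootstrap_strengths <- function(data, constraints = NULL, R = 200L,
                                seed = NULL, sd_floor = SD_FLOOR) {
  stopifnot(R >= 1L)
  data <- as.data.frame(data)
  cc <- stats::complete.cases(data)
  if (!all(cc)) {
    message("bootstrap structure learning on ", sum(cc),
            " complete rows (", sum(!cc), " incomplete dropped)")
    data <- data[cc, , drop = FALSE]
  }
  n <- nrow(data)
  if (n == 0L) stop("data is empty", call. = FALSE)
  nodes <- colnames(data)
  cons <- .check_constraints(constraints, nodes)
  if (!is.null(seed)) set.seed(as.integer(seed))
  N <- length(nodes)
  count <- matrix(0L, N, N, dimnames = list(nodes, nodes))
  failures <- 0L
  for (r in seq_len(R)) {
    idx <- sample.int(n, n, replace = TRUE)
    g <- tryCatch(
      hill_climb(data[idx, , drop = FALSE], cons, sd_floor = sd_floor),
      error = function(e) {
        message("bootstrap replicate ", r, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(g)) {
      failures <- failures + 1L
      next
    }
    count <- count + g$amat
  }
  R_ok <- R - failures
  if (R_ok == 0L) stop("all bootstrap replicates failed", call. = FALSE)
  rows <- NULL
  for (a in seq_len(N - 1L)) {
    for (b in (a + 1L):N) {
      pair_n <- count[a, b] + count[b, a]
      if (pair_n == 0L) next
      # majority direction; exact ties oriented from the lower-index node
      if (count[a, b] >= count[b, a]) {
        from <- nodes[a]; to <- nodes[b]; fwd <- count[a, b]
      } else {
        from <- nodes[b]; to <- nodes[a]; fwd <- count[b, a]
      }
      rows <- rbind(rows, data.frame(
        from = from, to = to,
        strength = pair_n / R_ok,
        direction = fwd / pair_n
      ))
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(from = character(0), to = character(0),
                       strength = numeric(0), direction = numeric(0))
  }
  out <- strength_table(rows, replicates = R_ok, nodes = nodes)
  attr(out, "failures") <- failures
  out
}

#' @export
print.strength_table <- function(x, ...) {
  cat("Arc strengths from", attr(x, "replicates"), "replicates")
  if ((attr(x, "failures") %||% 0L) > 0L) {
    cat(" (", attr(x, "failures"), "failed )")
  }
  cat("\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Estimate the arc-inclusion threshold from the strengths
#'
#' A noiseless strength distribution is a two-point step: a fraction of
#' pairs never appears (strength 0) and the rest always appears (strength
#' 1). The estimator picks the fraction `f` of never-present pairs whose
#' ideal step CDF minimises the L1 distance to the empirical CDF of the
#' observed strengths (ties resolved toward the smaller `f`, hence the
#' smaller threshold), and places the inclusion threshold at the midpoint
#' between the largest strength below the cut and the smallest strength
#' above it.
#'
#' @param strengths A `"strength_table"`.
#' @return The threshold, a value in `[0, 1]` to use with
#'   [consensus_network()] (inclusive, `>=`).
#' @examples
#' st <- strength_table(data.frame(
#'   from = c("A", "B"), to = c("B", "C"),
#'   strength = c(0.1, 0.9), direction = c(1, 1)
#' ))
#' estimate_threshold(st)
#' @export
estimate_threshold <- function(strengths) {
  stopifnot(inherits(strengths, "strength_table"))
  s <- sort(strengths$strength)
  n <- length(s)
  if (n == 0L) stop("empty strength table", call. = FALSE)
  if (length(unique(s)) == 1L && n > 1L) {
    warning("all strengths identical; threshold uninformative, using 0.5",
            call. = FALSE)
    return(0.5)
  }
  # empirical CDF as a step function over knots [0, s..., 1]
  knots <- c(0, s, 1)
  widths <- diff(knots)
  levels <- c(seq(0L, n) / n) # F-hat on each inter-knot interval
  l1 <- vapply(seq(0L, n) / n, function(f) sum(widths * abs(levels - f)),
               numeric(1))
  f_hat <- (which.min(l1) - 1L) / n # which.min takes the first (smaller) tie
  k <- round(f_hat * n)
  lo <- if (k == 0L) 0 else s[k]
  hi <- if (k == n) 1 else s[k + 1L]
  (lo + hi) / 2
}

#' Assemble the consensus network from arc strengths
#'
#' Keeps every pair whose strength is at least `threshold` (inclusive, so a
#' reported cut of 0.85 retains arcs of strength exactly 0.85), oriented
#' along its majority direction. Majority directions from different
#' replicates can conflict and make the assembled graph cyclic; in that
#' case arcs lying on a cycle are dropped weakest-first (by strength, then
#' direction strength, then lexicographic order), each drop reported via
#' `message()`.
#'
#' @param strengths A `"strength_table"`.
#' @param threshold Inclusion threshold in `[0, 1]`; typically the output
#'   of [estimate_threshold()], or a fixed value such as 0.5 or 0.85 for
#'   sparser summary views.
#' @return A `"gbn_dag"`, with the retained strength rows in attribute
#'   `strengths` and any cycle-breaking drops in attribute `dropped`.
#' @export
consensus_network <- function(strengths, threshold) {
  stopifnot(inherits(strengths, "strength_table"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  keep <- strengths[strengths$strength >= threshold, , drop = FALSE]
  nodes <- attr(strengths, "nodes")
  amat <- matrix(0L, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  if (nrow(keep) > 0L) amat[cbind(keep$from, keep$to)] <- 1L
  dropped <- NULL
  # weakest-first cycle breaking
  ord <- order(keep$strength, keep$direction, keep$from, keep$to)
  while (is.null(.topo_order(amat))) {
    for (i in ord) {
      u <- keep$from[i]
      v <- keep$to[i]
      if (amat[u, v] == 1L &&
          .has_path(amat, match(v, nodes), match(u, nodes))) {
        amat[u, v] <- 0L
        message("cycle in consensus graph: dropping weakest arc ", u,
                " -> ", v, " (strength ", signif(keep$strength[i], 3), ")")
        dropped <- rbind(dropped, keep[i, ])
        break
      }
    }
  }
  out <- new_dag(nodes, amat)
  retained <- keep[amat[cbind(keep$from, keep$to)] == 1L, , drop = FALSE]
  attr(out, "strengths") <- retained
  attr(out, "dropped") <- dropped
  attr(out, "threshold") <- threshold
  out
}

#' One-call bootstrap consensus pipeline
#'
#' Convenience wrapper: [bootstrap_strengths()], then
#' [estimate_threshold()] unless a fixed threshold is given, then
#' [consensus_network()].
#'
#' @inheritParams bootstrap_strengths
#' @param threshold Fixed inclusion threshold, or `NULL` to estimate it
#'   from the strengths.
#' @return The consensus `"gbn_dag"` (with `strengths` and `threshold`
#'   attributes).
#' @export
averaged_network <- function(data, constraints = NULL, R = 200L,
                             seed = NULL, threshold = NULL,
                             sd_floor = SD_FLOOR) {
  st <- bootstrap_strengths(data, constraints, R = R, seed = seed,
                            sd_floor = sd_floor)
  thr <- threshold %||% estimate_threshold(st)
  consensus_network(st, thr)
}

#' Write arc strengths to TSV
#'
#' @param strengths A `"strength_table"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_strengths <- function(strengths, path) {
  stopifnot(inherits(strengths, "strength_table"))
  utils::write.table(as.data.frame(strengths), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
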