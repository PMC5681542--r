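# Greedy score-based structure search. Single-arc additions, deletions and
# reversals are evaluated against the decomposable BIC, so each candidate
# move costs at most two cached local scores.

#' Constrained hill-climbing structure learning
#'
#' Greedy search over DAGs maximising the total BIC ([score_network()]).
#' The search starts from the whitelist-only graph and repeatedly applies
#' the single arc addition, deletion or reversal that most improves the
#' score among moves that keep the graph acyclic, respect the blacklist and
#' never delete or reverse a whitelisted arc. It stops at a local maximum.
#'
#' Candidate moves are evaluated in lexicographic `(parent, child,
#' move-type)` order with move types ordered add < delete < reverse, and
#' only strictly improving moves (improvement above `tol`) are applied, so
#' the result is deterministic given the data, the constraints and the
#' column order. `seed` is accepted for interface symmetry with the
#' resampling functions; the search itself consumes no randomness.
#'
#' Rows with missing values are dropped before scoring (with a one-time
#' message): score-based search needs every candidate parent set of a node
#' evaluated on the same rows, otherwise the `O(n)` scaling of the Gaussian
#' log-likelihood makes moves that merely change the row count look like
#' improvements. Parameter estimation ([fit_ols()]) is less demanding and
#' keeps per-model listwise deletion.
#'
#' @param data Numeric data frame; columns are the network nodes.
#' @param constraints A `"gbn_constraints"` object (see [constraints()] and
#'   [malocclusion_constraints()]), or `NULL` for an unconstrained search.
#' @param seed Unused by the deterministic search; kept in the signature so
#'   callers can treat all learners uniformly.
#' @param tol Minimal score improvement for a move to be applied.
#' @param sd_floor Residual standard deviation floor, see [bic_local()].
#' @param max_iter Safety cap on the number of applied moves.
#' @return The learned `"gbn_dag"`, with attributes `score` (total BIC) and
#'   `iterations`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); y <- 3 * x + rnorm(200)
#' g <- hill_climb(data.frame(x = x, y = y))
#' arcs(g)
#' @export
hill_climb <- function(data, constraints = NULL, seed = NULL, tol = 1e-10,
                       sd_floor = SD_FLOOR, max_iter = 500L) {
  data <- as.data.frame(data)
  cc <- stats::complete.cases(data)
  if (!all(cc)) {
    message("structure search on ", sum(cc), " complete rows (",
            sum(!cc), " incomplete dropped)")
    data <- data[cc, , drop = FALSE]
  }
  ctx <- .score_context(data)
  nodes <- ctx$nodes
  N <- length(nodes)
  if (ctx$n_all < 1L) stop("data is empty", call. = FALSE)
  cons <- .check_constraints(constraints, nodes)

  wl <- matrix(FALSE, N, N, dimnames = list(nodes, nodes))
  if (nrow(cons$whitelist) > 0L) wl[cons$whitelist] <- TRUE
  bl <- matrix(FALSE, N, N, dimnames = list(nodes, nodes))
  if (nrow(cons$blacklist) > 0L) bl[cons$blacklist] <- TRUE

  cache <- new.env(parent = emptyenv())
  local_score <- function(child, pa_set) {
    key <- paste0(child, "|", paste(sort(pa_set), collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- .local_score(ctx, nodes[child], nodes[pa_set], sd_floor)$score
    cache[[key]] <- val
    val
  }

  amat <- matrix(0L, N, N, dimnames = list(nodes, nodes))
  if (nrow(cons$whitelist) > 0L) amat[cons$whitelist] <- 1L
  node_score <- vapply(seq_len(N), function(i) {
    local_score(i, which(amat[, i] == 1L))
  }, numeric(1))

  iter <- 0L
  repeat {
    best_delta <- tol
    best_move <- NULL
    for (p in seq_len(N)) {
      for (ch in seq_len(N)) {
        if (p == ch) next
        pa_ch <- which(amat[, ch] == 1L)
        if (amat[p, ch] == 0L) {
          # addition p -> ch
          if (bl[p, ch] || .has_path(amat, ch, p)) next
          delta <- local_score(ch, c(pa_ch, p)) - node_score[ch]
          if (is.finite(delta) && delta > best_delta) {
            best_delta <- delta
            best_move <- list(type = "add", p = p, ch = ch)
          }
        } else {
          if (wl[p, ch]) next
          # deletion p -> ch
          delta <- local_score(ch, setdiff(pa_ch, p)) - node_score[ch]
          if (is.finite(delta) && delta > best_delta) {
            best_delta <- delta
            best_move <- list(type = "delete", p = p, ch = ch)
          }
          # reversal p -> ch becomes ch -> p
          if (!bl[ch, p]) {
            amat[p, ch] <- 0L
            cyclic <- .has_path(amat, p, ch)
            amat[p, ch] <- 1L
            if (!cyclic) {
              pa_p <- which(amat[, p] == 1L)
              delta <- (local_score(ch, setdiff(pa_ch, p)) - node_score[ch]) +
                (local_score(p, c(pa_p, ch)) - node_score[p])
              if (is.finite(delta) && delta > best_delta) {
                best_delta <- delta
                best_move <- list(type = "reverse", p = p, ch = ch)
              }
            }
          }
        }
      }
    }
    if (is.null(best_move) || iter >= max_iter) break
    iter <- iter + 1L
    p <- best_move$p
    ch <- best_move$ch
    if (best_move$type == "add") {
      amat[p, ch] <- 1L
      node_score[ch] <- local_score(ch, which(amat[, ch] == 1L))
    } else if (best_move$type == "delete") {
      amat[p, ch] <- 0L
      node_score[ch] <- local_score(ch, which(amat[, ch] == 1L))
    } else {
      amat[p, ch] <- 0L
      amat[ch, p] <- 1L
      node_score[ch] <- local_score(ch, which(amat[, ch] == 1L))
      node_score[p] <- local_score(p, which(amat[, p] == 1L))
    }
  }

  out <- new_dag(nodes, amat)
  attr(out, "score") <- sum(node_score)
  attr(out, "iterations") <- iter
  out
}
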