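# Directed acyclic graph primitives used by structure learning, model
# averaging and inference. Graphs are stored as a node vector plus an
# integer adjacency matrix amat[from, to]; node order is significant and is
# the deterministic tie-breaking order everywhere in the package.

new_dag <- function(nodes, amat) {
  structure(list(nodes = nodes, amat = amat), class = "gbn_dag")
}

.normalize_arcs <- function(arcs) {
  if (is.null(arcs)) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  }
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs)
  if (is.character(arcs) && is.null(dim(arcs)) && length(arcs) == 2L) {
    arcs <- matrix(arcs, ncol = 2L)
  }
  if (!is.matrix(arcs) || ncol(arcs) != 2L) {
    stop("arcs must be a two-column (from, to) matrix or data frame",
         call. = FALSE)
  }
  storage.mode(arcs) <- "character"
  colnames(arcs) <- c("from", "to")
  arcs
}

#' Create a directed acyclic graph
#'
#' @param nodes Character vector of unique node names. The order is kept and
#'   used as the deterministic tie-breaking order by [hill_climb()] and
#'   [consensus_network()].
#' @param arcs Optional two-column character matrix or data frame of directed
#'   arcs `(from, to)`.
#'
#' @return An object of class `"gbn_dag"` with elements `nodes` and `amat`
#'   (integer adjacency matrix, `amat[from, to] == 1L`).
#' @examples
#' g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' arcs(g)
#' parents(g, "C")
#' @export
dag <- function(nodes, arcs = NULL) {
  if (!is.character(nodes) || length(nodes) == 0L || anyDuplicated(nodes) ||
      anyNA(nodes)) {
    stop("nodes must be a non-empty character vector without duplicates",
         call. = FALSE)
  }
  arcs <- .normalize_arcs(arcs)
  amat <- matrix(0L, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  if (nrow(arcs) > 0L) {
    bad <- !(arcs %in% nodes)
    if (any(bad)) {
      stop("unknown node(s) in arcs: ",
           paste(unique(arcs[bad]), collapse = ", "), call. = FALSE)
    }
    if (any(arcs[, 1L] == arcs[, 2L])) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    amat[arcs] <- 1L
  }
  if (is.null(.topo_order(amat))) {
    stop("arcs define a cyclic graph; a DAG is required", call. = FALSE)
  }
  new_dag(nodes, amat)
}

# Kahn's algorithm; returns node indices in topological order or NULL if the
# graph is cyclic. Deterministic: always removes the lowest-index root first.
.topo_order <- function(amat) {
  n <- nrow(amat)
  indeg <- colSums(amat)
  order <- integer(0)
  avail <- which(indeg == 0L)
  while (length(avail) > 0L) {
    v <- avail[1L]
    avail <- avail[-1L]
    order <- c(order, v)
    ch <- which(amat[v, ] == 1L)
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(order) < n) NULL else order
}

# TRUE iff a directed path from `from` to `to` exists (indices).
.has_path <- function(amat, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(amat))
  stack <- from
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    ch <- which(amat[v, ] == 1L)
    if (any(ch == to)) return(TRUE)
    stack <- c(stack, ch[!seen[ch]])
  }
  FALSE
}

#' @rdname dag
#' @param x A `"gbn_dag"` object.
#' @export
arcs <- function(x) UseMethod("arcs")

#' @export
arcs.gbn_dag <- function(x) {
  idx <- which(x$amat == 1L, arr.ind = TRUE)
  out <- cbind(from = x$nodes[idx[, 1L]], to = x$nodes[idx[, 2L]])
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' @rdname dag
#' @param node A node name.
#' @export
parents <- function(x, node) {
  stopifnot(inherits(x, "gbn_dag"), node %in% x$nodes)
  x$nodes[x$amat[, node] == 1L]
}

#' @rdname dag
#' @export
children <- function(x, node) {
  stopifnot(inherits(x, "gbn_dag"), node %in% x$nodes)
  x$nodes[x$amat[node, ] == 1L]
}

#' @export
print.gbn_dag <- function(x, ...) {
  a <- arcs(x)
  cat("Directed acyclic graph over", length(x$nodes), "nodes,",
      nrow(a), "arcs\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(a) > 0L) {
    cat("  arcs: ", paste(a[, 1L], "->", a[, 2L], collapse = "; "), "\n")
  }
  invisible(x)
}

#' Structural Hamming distance between two graphs
#'
#' Counts, over all unordered node pairs, how many are adjacent in exactly
#' one of the two graphs (skeleton distance, the structure-recovery metric
#' used by the simulation studies). With `skeleton = FALSE`, arcs present in
#' both skeletons but oriented differently add one each.
#'
#' @param a,b `"gbn_dag"` objects over the same node set.
#' @param skeleton Compare undirected skeletons only (default `TRUE`).
#' @return A non-negative integer count.
#' @export
shd <- function(a, b, skeleton = TRUE) {
  stopifnot(inherits(a, "gbn_dag"), inherits(b, "gbn_dag"))
  if (!setequal(a$nodes, b$nodes)) {
    stop("graphs must share the same node set", call. = FALSE)
  }
  bm <- b$amat[a$nodes, a$nodes]
  ska <- (a$amat + t(a$amat)) > 0L
  skb <- (bm + t(bm)) > 0L
  d <- sum(ska != skb) / 2L
  if (!skeleton) {
    both <- ska & skb
    flipped <- both & (a$amat != bm) & (t(a$amat) != t(bm))
    d <- d + sum(flipped[upper.tri(flipped)] | t(flipped)[upper.tri(flipped)])
  }
  as.integer(d)
}

#' Whitelist/blacklist constraint sets for structure learning
#'
#' A whitelist forces arcs (with their direction) into every learned graph;
#' a blacklist forbids specific directed arcs. The whitelist must itself be
#' acyclic and must not intersect the blacklist.
#'
#' @param whitelist,blacklist Two-column character matrices or data frames of
#'   directed arcs `(from, to)`, or `NULL`.
#' @return An object of class `"gbn_constraints"`.
#' @seealso [malocclusion_constraints()] for the craniofacial tier defaults.
#' @export
constraints <- function(whitelist = NULL, blacklist = NULL) {
  wl <- .normalize_arcs(whitelist)
  bl <- .normalize_arcs(blacklist)
  if (nrow(wl) > 0L && any(wl[, 1L] == wl[, 2L])) {
    stop("whitelist contains a self-loop", call. = FALSE)
  }
  wl <- unique(wl)
  bl <- unique(bl)
  if (nrow(wl) > 0L && nrow(bl) > 0L) {
    key <- function(m) paste(m[, 1L], m[, 2L], sep = "\r")
    if (any(key(wl) %in% key(bl))) {
      stop("whitelist and blacklist overlap", call. = FALSE)
    }
  }
  structure(list(whitelist = wl, blacklist = bl), class = "gbn_constraints")
}

#' @export
print.gbn_constraints <- function(x, ...) {
  cat("Structure-learning constraints:",
      nrow(x$whitelist), "whitelisted,",
      nrow(x$blacklist), "blacklisted arcs\n")
  invisible(x)
}

# Validates a constraint set against a node vector; errors on unknown nodes
# or a cyclic whitelist. Returns the (checked) constraint set.
.check_constraints <- function(cons, nodes) {
  if (is.null(cons)) cons <- constraints()
  stopifnot(inherits(cons, "gbn_constraints"))
  all_named <- c(cons$whitelist, cons$blacklist)
  unknown <- setdiff(all_named, nodes)
  if (length(unknown) > 0L) {
    stop("constraints mention unknown node(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  # whitelist alone must be satisfiable
  dag(nodes, cons$whitelist)
  cons
}

#' Tiered prior-knowledge constraints for the craniofacial variables
#'
#' Builds the whitelist/blacklist encoding the clinical prior knowledge used
#' throughout the analysis: craniofacial difference variables cannot point
#' into the elapsed time `dT`, into `Treatment` or into the prognosis
#' `Growth`; nothing points into `dT` or `Treatment` (patients are treated or
#' not for the whole observation window, and elapsed time depends on nothing
#' measured); and the arcs `dANB -> dIMPA`, `dPPPM -> dIMPA` and
#' `dT -> Growth` are forced, the first two encoding dentoalveolar
#' compensation of the incisors and the last allowing the prognosis to change
#' with the length of the observation window.
#'
#' @param nodes Character vector of variables in the data; constraints are
#'   restricted to the nodes actually present, so the helper also works for
#'   subgroup tables without the `Treatment` column.
#' @param exogenous Names of root variables nothing may point into.
#' @param outcome Name of the prognosis variable features may not point into.
#' @return A `"gbn_constraints"` object.
#' @export
malocclusion_constraints <- function(nodes,
                                     exogenous = c("dT", "Treatment"),
                                     outcome = "Growth") {
  exogenous <- intersect(exogenous, nodes)
  outcome <- intersect(outcome, nodes)
  features <- setdiff(nodes, c(exogenous, outcome))
  bl <- NULL
  # nothing points into the exogenous tier
  for (ex in exogenous) {
    bl <- rbind(bl, cbind(setdiff(nodes, ex), ex))
  }
  # features do not determine the prognosis
  if (length(outcome) == 1L && length(features) > 0L) {
    bl <- rbind(bl, cbind(features, outcome))
  }
  wl <- NULL
  wl_pairs <- rbind(c("dANB", "dIMPA"), c("dPPPM", "dIMPA"),
                    c("dT", "Growth"))
  for (i in seq_len(nrow(wl_pairs))) {
    if (all(wl_pairs[i, ] %in% nodes)) wl <- rbind(wl, wl_pairs[i, ])
  }
  constraints(whitelist = wl, blacklist = bl)
}
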