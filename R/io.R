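# Interchange formats: DAGs as DOT and arc-list TSV, fitted parameters as
# JSON.

#' Export a DAG
#'
#' `write_dot()` writes Graphviz DOT, with arc pen widths proportional to
#' strength when the DAG carries consensus strengths (or when a strength
#' table is supplied); `write_arcs()` writes a plain `(from, to)` TSV.
#'
#' @param x A `"gbn_dag"`.
#' @param path Output file path.
#' @param strengths Optional `"strength_table"` used for arc thickness.
#' @return `path`, invisibly.
#' @export
write_dot <- function(x, path, strengths = NULL) {
  stopifnot(inherits(x, "gbn_dag"))
  st <- strengths %||% attr(x, "strengths")
  lines <- c("digraph consensus {",
             paste0("  \"", x$nodes, "\";"))
  a <- arcs(x)
  for (i in seq_len(nrow(a))) {
    w <- 1
    if (!is.null(st)) {
      hit <- st$from == a[i, 1L] & st$to == a[i, 2L]
      if (any(hit)) w <- 0.5 + 3 * st$strength[hit][1L]
    }
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [penwidth=%.2f];",
                              a[i, 1L], a[i, 2L], w))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' @rdname write_dot
#' @export
write_arcs <- function(x, path) {
  stopifnot(inherits(x, "gbn_dag"))
  utils::write.table(as.data.frame(arcs(x)), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DAG from an arc-list TSV
#'
#' @param path TSV with `from`, `to` columns (as written by
#'   [write_arcs()]).
#' @param nodes Node set; defaults to the nodes mentioned in the file.
#' @return A `"gbn_dag"`.
#' @export
read_arcs <- function(path, nodes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(df$from, df$to)))
  dag(nodes, as.matrix(df[c("from", "to")]))
}

#' Read/write fitted network parameters as JSON
#'
#' Serialises a `"gbn_fit"` as a JSON list of local models (node, parents,
#' intercept, coefficients, residual_sd) plus the node order, sample size
#' and binary-node set; `read_fit_json()` restores it.
#'
#' @param fit A `"gbn_fit"`.
#' @param path File path.
#' @return `write_fit_json()`: `path`, invisibly. `read_fit_json()`: a
#'   `"gbn_fit"`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "gbn_fit"))
  payload <- list(
    nodes = fit$dag$nodes,
    sample_size = fit$sample_size,
    binary_nodes = fit$binary_nodes,
    growth_rule = as.list(attr(fit, "growth_rule")),
    locals = lapply(fit$locals, function(lm) {
      list(node = lm$node, parents = as.list(lm$parents),
           intercept = lm$intercept,
           coefficients = as.list(lm$coefficients),
           residual_sd = lm$residual_sd)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  locals <- lapply(payload$locals, function(lm) {
    pa <- unlist(lm$parents) %||% character(0)
    list(intercept = lm$intercept,
         coefficients = stats::setNames(
           as.numeric(unlist(lm$coefficients) %||% numeric(0)),
           as.character(pa)),
         residual_sd = lm$residual_sd)
  })
  names(locals) <- vapply(payload$locals, `[[`, "", "node")
  fit <- gbn_network(locals,
                     binary_nodes = as.character(unlist(payload$binary_nodes)
                                                 %||% character(0)),
                     nodes = unlist(payload$nodes))
  fit$sample_size <- if (is.null(payload$sample_size)) NA_integer_ else
    as.integer(payload$sample_size)
  if (length(payload$growth_rule) > 0L) {
    attr(fit, "growth_rule") <- unlist(payload$growth_rule)
  }
  fit
}

#' Write a query specification or result as JSON
#'
#' Small helpers for scripting: a query document holds `event`,
#' `evidence`, `n` and `seed`; [run_query_file()] executes it against a
#' fitted network and returns the `"gbn_query"`.
#'
#' @param fit A `"gbn_fit"`.
#' @param path Path to a JSON query document.
#' @return The `"gbn_query"` result.
#' @export
run_query_file <- function(fit, path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  to_pred <- function(p) lapply(p, function(v) unlist(v))
  event <- if (is.character(spec$event) || (is.list(spec$event) &&
                                            is.null(names(spec$event)))) {
    as.character(unlist(spec$event))
  } else {
    to_pred(spec$event)
  }
  conditional_query(fit, event = event,
                    evidence = to_pred(spec$evidence),
                    n = spec$n %||% 1e4,
                    seed = spec$seed)
}

#' Write a query result as JSON
#'
#' @param result A `"gbn_query"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_query_result <- function(result, path) {
  stopifnot(inherits(result, "gbn_query"))
  jsonlite::write_json(list(estimate = result$estimate,
                            mc_se = result$mc_se,
                            n_matched_evidence = result$n_matched_evidence,
                            n_samples = result$n_samples,
                            type = result$type),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
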