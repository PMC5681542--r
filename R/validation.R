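# k-fold cross-validation of the full learning pipeline: per-variable
# predictive correlation and prognosis classification error.

#' Misclassification fraction
#'
#' The predictive classification error: the fraction of positions at which
#' the observed and predicted binary sequences disagree (the complement of
#' predictive accuracy).
#'
#' @param observed,predicted Binary (0/1) vectors of equal length.
#' @return A value in `[0, 1]`.
#' @examples
#' classification_error(c(1, 0, 1, 0), c(1, 0, 0, 1)) # 0.5
#' @export
classification_error <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) == 0L) stop("empty sequences", call. = FALSE)
  if (anyNA(observed) || anyNA(predicted)) {
    stop("missing values not allowed", call. = FALSE)
  }
  mean(observed != predicted)
}

# Conditional mean of `target` given the other columns, vectorized over
# rows. `use` names the evidence columns actually conditioned on (rows with
# a missing prognosis condition on everything but Growth).
.predict_conditional_mean <- function(mom, target, rows, use) {
  if (length(use) == 0L) return(rep(unname(mom$mean[target]), nrow(rows)))
  S_ee <- mom$cov[use, use, drop = FALSE]
  S_te <- mom$cov[target, use, drop = FALSE]
  w <- .solve_psd(S_ee, t(S_te))
  dev <- t(as.matrix(rows[, use, drop = FALSE])) - mom$mean[use]
  drop(unname(mom$mean[target]) + crossprod(dev, w))
}

#' Cross-validated predictive accuracy of the learning pipeline
#'
#' Splits the rows into `k` folds (seeded uniform shuffle, sizes differing
#' by at most one; optionally stratified by `Treatment`). For each fold the
#' structure (single hill-climbing search or bootstrap-averaged consensus)
#' and the parameters are learned on the training rows only; each variable
#' of each test row is then predicted from all its other variables via the
#' exact Gaussian conditional mean of the fitted network. The pooled
#' (observed, predicted) pairs give the *predictive correlation*
#' ([pearson_r()]) per continuous variable; `Growth` predictions are
#' thresholded at 0.5 and summarised by [classification_error()].
#'
#' Rows with a missing prognosis are predicted conditioning on everything
#' except `Growth` and are excluded from the `Growth` metric only.
#'
#' @param data A rate table (or compatible numeric data frame) with at
#'   least `2k` rows.
#' @param constraints A `"gbn_constraints"` or `NULL`.
#' @param k Number of folds (default 10).
#' @param averaging Learn a bootstrap consensus structure per fold instead
#'   of a single hill-climbing search.
#' @param R,threshold Bootstrap replicates and inclusion threshold for the
#'   averaged variant (`threshold = NULL` estimates it per fold).
#' @param stratify Balance `Treatment` levels across folds.
#' @param seed Integer seed for the fold shuffle (and the per-fold
#'   bootstraps).
#' @param sd_floor Passed to the learners.
#' @return A `"cv_report"`: `predictive_correlation` (named vector over the
#'   continuous variables), `classification_error` (for `Growth`, `NA` if
#'   absent), `fold_assignments`, `k`, and the pooled `pairs` data frame
#'   (`fold`, `row`, `variable`, `observed`, `predicted`) for audit.
#' @export
cross_validate <- function(data, constraints = NULL, k = 10L,
                           averaging = FALSE, R = 200L, threshold = NULL,
                           stratify = FALSE, seed = NULL,
                           sd_floor = SD_FLOOR) {
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n < 2L * k) stop("need at least 2k rows for ", k, " folds",
                       call. = FALSE)
  nodes <- colnames(data)
  cons <- .check_constraints(constraints, nodes)
  binary <- intersect(c("Treatment", "Growth"), nodes)
  class_var <- intersect("Growth", nodes)
  if (!is.null(seed)) set.seed(as.integer(seed))
  fold <- integer(n)
  if (stratify && "Treatment" %in% nodes) {
    for (lev in unique(data$Treatment)) {
      idx <- which(data$Treatment == lev)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  ids <- rownames(data) %||% as.character(seq_len(n))

  pairs <- NULL
  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    if (nrow(test) == 0L) next
    g <- tryCatch({
      if (averaging) {
        suppressMessages(averaged_network(train, cons, R = R,
                                          threshold = threshold,
                                          sd_floor = sd_floor))
      } else {
        suppressMessages(hill_climb(train, cons, sd_floor = sd_floor))
      }
    }, error = function(e) {
      stop("learning failed on the training data of fold ", f, ": ",
           conditionMessage(e), call. = FALSE)
    })
    fit <- tryCatch(fit_ols(g, train, sd_floor = sd_floor),
                    error = function(e) {
                      stop("fold ", f, " too small to fit: ",
                           conditionMessage(e), call. = FALSE)
                    })
    mom <- implied_moments(fit)
    growth_na <- if ("Growth" %in% nodes) is.na(test$Growth) else
      rep(FALSE, nrow(test))
    for (target in nodes) {
      for (grp in list(which(!growth_na), which(growth_na))) {
        if (length(grp) == 0L) next
        use <- setdiff(nodes, target)
        if (any(growth_na[grp])) use <- setdiff(use, "Growth")
        if (target == "Growth" && any(growth_na[grp])) next
        pred <- .predict_conditional_mean(mom, target,
                                          test[grp, , drop = FALSE], use)
        pairs <- rbind(pairs, data.frame(
          fold = f, row = ids[fold == f][grp], variable = target,
          observed = test[[target]][grp], predicted = pred
        ))
      }
    }
  }

  predcor <- stats::setNames(numeric(0), character(0))
  for (v in setdiff(nodes, binary)) {
    pv <- pairs[pairs$variable == v, ]
    predcor[v] <- pearson_r(pv$observed, pv$predicted)
  }
  class_err <- NA_real_
  if (length(class_var) == 1L) {
    pv <- pairs[pairs$variable == "Growth", ]
    if (nrow(pv) > 0L) {
      class_err <- classification_error(pv$observed,
                                        as.numeric(pv$predicted >= 0.5))
    }
  }
  structure(list(predictive_correlation = predcor,
                 classification_error = class_err,
                 fold_assignments = stats::setNames(fold, ids),
                 k = as.integer(k), pairs = pairs),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(x$k, "-fold cross-validation\n", sep = "")
  cat("  predictive correlations:\n")
  for (v in names(x$predictive_correlation)) {
    cat(sprintf("    %-10s %6.3f\n", v, x$predictive_correlation[v]))
  }
  if (!is.na(x$classification_error)) {
    cat(sprintf("  Growth classification error: %.3f (accuracy %.3f)\n",
                x$classification_error, 1 - x$classification_error))
  }
  invisible(x)
}

#' Export a cross-validation report
#'
#' `write_cv_report()` writes the metrics as JSON; `write_cv_pairs()` dumps
#' the pooled (observed, predicted) pairs as CSV for audit.
#'
#' @param report A `"cv_report"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  jsonlite::write_json(list(
    k = report$k,
    predictive_correlation = as.list(report$predictive_correlation),
    classification_error = report$classification_error
  ), path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_cv_report
#' @export
write_cv_pairs <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  utils::write.csv(report$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
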