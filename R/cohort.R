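# Two-visit cohort data model: CSV ingestion with per-row diagnostics,
# atlas adjustment against a normative reference table, and the raw-to-
# difference transform that produces the variables the network is learned
# on.

#' @name cephnet-features
#' @title Cephalometric feature set
#' @description The six craniofacial measurements modelled by the package:
#'   `ANB`, `IMPA`, `PPPM` (degrees) and `CoA`, `GoPg`, `CoGo`
#'   (millimetres). `ceph_features()` returns their canonical order.
#' @return Character vector of feature names.
#' @export
ceph_features <- function() c("ANB", "IMPA", "PPPM", "CoA", "GoPg", "CoGo")

.cohort_columns <- function() {
  c("id", "treated", "growth", "age_t1", "age_t2",
    paste0(ceph_features(), "_t1"), paste0(ceph_features(), "_t2"))
}

new_cohort <- function(df, provenance = "raw") {
  structure(df, provenance = provenance,
            class = c("ceph_cohort", "data.frame"))
}

#' Validate a two-visit cohort
#'
#' Checks the cohort invariants: unique patient ids, complete feature
#' values at both visits, `age_t2 > age_t1` for every patient, binary
#' treated/growth codes, and prognosis missing only for treated patients.
#' All violations are collected and reported together, each naming the
#' offending patient.
#'
#' @param cohort A `"ceph_cohort"` (or compatible data frame with the
#'   columns of [read_cohort()]).
#' @return The validated cohort, invisibly; errors otherwise.
#' @export
validate_cohort <- function(cohort) {
  cols <- .cohort_columns()
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  probs <- character(0)
  id <- as.character(cohort$id)
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0L) {
    probs <- c(probs, paste0("duplicated patient id(s): ",
                             paste(dup, collapse = ", ")))
  }
  bad_age <- !(is.finite(cohort$age_t1) & is.finite(cohort$age_t2) &
                 cohort$age_t1 > 0 & cohort$age_t2 > cohort$age_t1)
  if (any(bad_age)) {
    probs <- c(probs, paste0("age_t2 <= age_t1 (or non-positive age) for: ",
                             paste(id[bad_age], collapse = ", ")))
  }
  feat_cols <- c(paste0(ceph_features(), "_t1"),
                 paste0(ceph_features(), "_t2"))
  bad_feat <- rowSums(!is.finite(as.matrix(cohort[feat_cols]))) > 0L
  if (any(bad_feat)) {
    probs <- c(probs, paste0("missing/non-finite feature value(s) for: ",
                             paste(id[bad_feat], collapse = ", ")))
  }
  bad_tr <- !(cohort$treated %in% c(0, 1))
  if (any(bad_tr)) {
    probs <- c(probs, paste0("treated flag not 0/1 for: ",
                             paste(id[bad_tr], collapse = ", ")))
  }
  bad_gr <- !(cohort$growth %in% c(0, 1) | is.na(cohort$growth))
  if (any(bad_gr)) {
    probs <- c(probs, paste0("growth flag not 0/1/missing for: ",
                             paste(id[bad_gr], collapse = ", ")))
  }
  orphan <- is.na(cohort$growth) & cohort$treated %in% 0
  if (any(orphan)) {
    probs <- c(probs, paste0("growth missing for untreated patient(s): ",
                             paste(id[orphan], collapse = ", ")))
  }
  if (length(probs) > 0L) {
    stop("invalid cohort:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(cohort)
}

#' Column-name mapping for cohort CSV files
#'
#' Maps the canonical cohort column names onto the names actually used in a
#' CSV file, so files from other groups can be ingested without renaming.
#'
#' @param ... Named overrides, canonical = file name, e.g.
#'   `cohort_dialect(id = "patient")`.
#' @return A named character vector (canonical name -> file column name).
#' @export
cohort_dialect <- function(...) {
  dialect <- stats::setNames(.cohort_columns(), .cohort_columns())
  override <- c(...)
  if (length(override) > 0L) {
    unknown <- setdiff(names(override), names(dialect))
    if (length(unknown) > 0L) {
      stop("unknown canonical column(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    dialect[names(override)] <- override
  }
  dialect
}

#' Read a two-visit cohort from CSV
#'
#' Expects one row per patient with columns `id, treated, growth, age_t1,
#' age_t2, ANB_t1 ... CoGo_t1, ANB_t2 ... CoGo_t2` (names remappable via
#' `dialect`). A missing prognosis is encoded as an empty `growth` field and
#' is only allowed for treated patients. All row-level violations are
#' reported together with the offending patient ids.
#'
#' @param path Path to the CSV file.
#' @param dialect Column-name mapping from [cohort_dialect()].
#' @param multiple How to handle several rows for the same patient:
#'   `"error"` (default; the model uses exactly one difference per patient)
#'   or `"first_last"`, which keeps the earliest visit-1 and the latest
#'   visit-2 record of each patient.
#' @return A validated `"ceph_cohort"` with attribute
#'   `provenance = "raw"`.
#' @export
read_cohort <- function(path, dialect = cohort_dialect(),
                        multiple = c("error", "first_last")) {
  multiple <- match.arg(multiple)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- dialect[!(dialect %in% names(raw))]
  if (length(missing_cols) > 0L) {
    stop("cohort file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- raw[, dialect]
  names(df) <- names(dialect)
  df$id <- as.character(df$id)
  for (col in setdiff(names(df), "id")) df[[col]] <- as.numeric(df[[col]])
  if (anyDuplicated(df$id) && multiple == "first_last") {
    df <- do.call(rbind, lapply(split(df, df$id), function(rows) {
      rows <- rows[order(rows$age_t1), ]
      first <- rows[1L, ]
      last <- rows[which.max(rows$age_t2), ]
      first[c("age_t2", paste0(ceph_features(), "_t2"))] <-
        last[c("age_t2", paste0(ceph_features(), "_t2"))]
      first
    }))
    rownames(df) <- NULL
  }
  out <- new_cohort(df, provenance = "raw")
  validate_cohort(out)
  out
}

#' Write a cohort to CSV
#'
#' Writes the same dialect [read_cohort()] reads; a missing prognosis
#' becomes an empty field.
#'
#' @param cohort A `"ceph_cohort"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[.cohort_columns()], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Compute difference (rate-of-change) variables
#'
#' Transforms a two-visit cohort into the node-ready rate table: one row per
#' patient with `dT = age_t2 - age_t1`, `dY = Y_t2 - Y_t1` for each of the
#' six features, and the 0/1 `Treatment` and `Growth` flags. These
#' differences, with `dT` as an ordinary regressor, are the variables the
#' Bayesian network is learned on.
#'
#' @param cohort A validated `"ceph_cohort"`.
#' @return A `"rate_table"` data frame with the fixed column layout
#'   `dT, Treatment, Growth, dANB, dIMPA, dPPPM, dCoA, dGoPg, dCoGo` and
#'   patient ids as row names.
#' @examples
#' cohort <- simulate_cohort(generator_config(n_patients = 20, seed = 1))
#' head(compute_differences(cohort))
#' @export
compute_differences <- function(cohort) {
  validate_cohort(cohort)
  feats <- ceph_features()
  out <- data.frame(
    dT = cohort$age_t2 - cohort$age_t1,
    Treatment = as.numeric(cohort$treated),
    Growth = as.numeric(cohort$growth)
  )
  for (f in feats) {
    out[[paste0("d", f)]] <-
      cohort[[paste0(f, "_t2")]] - cohort[[paste0(f, "_t1")]]
  }
  out <- out[c("dT", "Treatment", "Growth",
               "dANB", "dIMPA", "dPPPM", "dCoA", "dGoPg", "dCoGo")]
  rownames(out) <- as.character(cohort$id)
  structure(out, class = c("rate_table", "data.frame"))
}

#' Read a normative reference table
#'
#' Reads a CSV with columns `feature, age, value` tabulating normal
#' cephalometric values by age (an "atlas"), for use with
#' [adjust_by_reference()]. Every feature of the cohort must be present
#' with at least two distinct, strictly increasing ages.
#'
#' @param path Path to the CSV file.
#' @return A `"ceph_reference"` object (list of per-feature age/value
#'   tables).
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("feature", "age", "value")
  if (!all(needed %in% names(df))) {
    stop("reference file needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  reference_table(df)
}

#' Build a normative reference table from a data frame
#'
#' @param df Data frame with columns `feature`, `age`, `value`.
#' @return A `"ceph_reference"` object.
#' @rdname read_reference
#' @export
reference_table <- function(df) {
  missing_feat <- setdiff(ceph_features(), unique(df$feature))
  if (length(missing_feat) > 0L) {
    stop("reference lacks feature(s): ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  }
  entries <- lapply(split(df[c("age", "value")], df$feature), function(tab) {
    tab <- tab[order(tab$age), ]
    if (nrow(tab) < 2L || anyDuplicated(tab$age)) {
      stop("each feature needs at least two distinct tabulated ages",
           call. = FALSE)
    }
    tab
  })
  structure(list(entries = entries), class = "ceph_reference")
}

# Interpolated normative value; NA outside the tabulated range.
.reference_value <- function(reference, feature, age) {
  tab <- reference$entries[[feature]]
  stats::approx(tab$age, tab$value, xout = age, rule = 1)$y
}

#' Adjust a cohort against normative reference values
#'
#' Replaces each visit value by its deviation from the age-matched normative
#' value, `value - reference(feature, age)`, with the reference evaluated by
#' linear interpolation between its tabulated ages. Extrapolation outside
#' the tabulated age range is an error (atlas tables are sparse and monotone
#' trends are not guaranteed), reported with the patient and feature.
#'
#' @param cohort A validated `"ceph_cohort"`.
#' @param reference A `"ceph_reference"` from [read_reference()] or
#'   [reference_table()].
#' @return A new `"ceph_cohort"` with `provenance = "adjusted"`.
#' @export
adjust_by_reference <- function(cohort, reference) {
  validate_cohort(cohort)
  stopifnot(inherits(reference, "ceph_reference"))
  out <- as.data.frame(cohort)
  gaps <- character(0)
  for (f in ceph_features()) {
    for (visit in c("t1", "t2")) {
      age <- out[[paste0("age_", visit)]]
      ref <- .reference_value(reference, f, age)
      uncovered <- is.na(ref)
      if (any(uncovered)) {
        gaps <- c(gaps, paste0(out$id[uncovered], "/", f, "@", visit))
      }
      col <- paste0(f, "_", visit)
      out[[col]] <- out[[col]] - ref
    }
  }
  if (length(gaps) > 0L) {
    stop("reference does not cover: ",
         paste(utils::head(gaps, 10L), collapse = ", "),
         if (length(gaps) > 10L) " ..." else "", call. = FALSE)
  }
  new_cohort(out, provenance = "adjusted")
}

#' @export
print.ceph_cohort <- function(x, n = 6L, ...) {
  cat("Two-visit cohort of", nrow(x), "patients (",
      sum(x$treated == 1), "treated /", sum(x$treated == 0), "untreated ),",
      "provenance:", attr(x, "provenance"), "\n")
  print(utils::head(as.data.frame(x)[seq_len(min(8L, ncol(x)))], n))
  if (nrow(x) > n) cat("# ...", nrow(x) - n, "more patients\n")
  invisible(x)
}
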