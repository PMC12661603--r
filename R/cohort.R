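#' Declare a data frame as a cohort feature table
#'
#' Tags a data frame with the column roles used throughout the package: which
#' columns are clustering/distance features (and whether each is numeric or
#' categorical), which column identifies rows, and which columns are
#' demographics carried along for subgroup reporting but excluded from all
#' distance and clustering computations.
#'
#' @param data A data frame, one row per patient/encounter.
#' @param features Character vector of feature column names. Defaults to every
#'   numeric column not otherwise assigned a role.
#' @param id Name of a unique row-identifier column, or `NULL` to use row
#'   position. Identifiers must be unique.
#' @param kinds Named character vector mapping feature names to `"numeric"` or
#'   `"categorical"`. Unnamed features default to `"numeric"` for numeric
#'   columns and `"categorical"` otherwise.
#' @param demographics Character vector of demographic columns (kept as
#'   metadata, never entering distances or clustering).
#' @param outcome Optional name of a binary outcome column.
#'
#' @return A tibble of class `covr_cohort` with role attributes. All feature
#'   columns are checked for missing values: rows with missing features are an
#'   error (ingestion never drops rows silently; see [read_cohort()] for
#'   imputation options).
#' @export
#' @examples
#' coh <- as_cohort(data.frame(x = c(0, 3), y = c(0, 4)))
#' cohort_features(coh)
as_cohort <- function(data, features = NULL, id = NULL, kinds = NULL,
                      demographics = NULL, outcome = NULL) {
  data <- tibble::as_tibble(data)
  reserved <- c(id, demographics, outcome)
  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        reserved)
  }
  missing_cols <- setdiff(c(features, reserved), names(data))
  if (length(missing_cols)) {
    abort(paste0("Columns not found in data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (length(features) < 1L) abort("A cohort needs at least one feature column.")
  if (length(intersect(features, reserved))) {
    abort("Feature columns must be disjoint from id/demographic/outcome columns.")
  }
  kind_of <- function(col) if (is.numeric(data[[col]])) "numeric" else "categorical"
  resolved <- vapply(features, kind_of, character(1))
  if (!is.null(kinds)) {
    bad <- setdiff(kinds, c("numeric", "categorical"))
    if (length(bad)) abort("Feature kinds must be 'numeric' or 'categorical'.")
    resolved[names(kinds)] <- kinds
  }
  for (col in features) {
    if (resolved[[col]] == "numeric" && !is.numeric(data[[col]])) {
      abort(paste0("Column '", col, "' is declared numeric but is not."))
    }
    if (anyNA(data[[col]])) {
      abort(paste0("Feature column '", col, "' has missing values; ",
                   "impute or filter before building a cohort."))
    }
  }
  if (!is.null(id)) {
    if (anyNA(data[[id]]) || anyDuplicated(data[[id]])) {
      abort(paste0("Row identifiers in '", id, "' must be unique and non-missing."))
    }
  }
  structure(
    data,
    class = c("covr_cohort", class(data)),
    cohort_features = features,
    cohort_kinds = resolved,
    cohort_id = id,
    cohort_demographics = demographics,
    cohort_outcome = outcome
  )
}

#' Cohort role accessors
#'
#' @param cohort A `covr_cohort` built by [as_cohort()].
#' @return `cohort_features()` the feature column names; `cohort_kinds()` a
#'   named vector of per-feature kinds; `cohort_ids()` the row identifiers
#'   (row positions when no id column was declared).
#' @export
cohort_features <- function(cohort) attr(cohort, "cohort_features")

#' @rdname cohort_features
#' @export
cohort_kinds <- function(cohort) attr(cohort, "cohort_kinds")

#' @rdname cohort_features
#' @export
cohort_ids <- function(cohort) {
  id <- attr(cohort, "cohort_id")
  if (is.null(id)) seq_len(nrow(cohort)) else cohort[[id]]
}

assert_cohort <- function(cohort) {
  if (!inherits(cohort, "covr_cohort")) {
    cohort <- as_cohort(cohort)
  }
  cohort
}

# numeric feature matrix (numeric kinds only); errors if asked for categorical
feature_matrix <- function(cohort, numeric_only = TRUE) {
  kinds <- cohort_kinds(cohort)
  feats <- cohort_features(cohort)
  if (numeric_only) feats <- feats[kinds[feats] == "numeric"]
  as.matrix(as.data.frame(cohort)[, feats, drop = FALSE])
}

#' @export
print.covr_cohort <- function(x, ...) {
  kinds <- cohort_kinds(x)
  cat(sprintf("# A cohort: %d rows, %d features (%d numeric, %d categorical)\n",
              nrow(x), length(cohort_features(x)),
              sum(kinds == "numeric"), sum(kinds == "categorical")))
  NextMethod()
  invisible(x)
}
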