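#' Read a cohort feature table from CSV
#'
#' Loads a flat de-identified cohort export (one row per patient, header row)
#' and tags column roles. Rows with missing feature values are an error by
#' default — never silently dropped — or mean/mode imputed on request, with a
#' message reporting how many values were filled.
#'
#' @param path CSV file path.
#' @param features,id,kinds,demographics,outcome Column roles, as in
#'   [as_cohort()].
#' @param impute `"none"` (reject missing feature values, the default) or
#'   `"mean_mode"` (mean for numeric features, most frequent level for
#'   categorical ones).
#' @return A `covr_cohort` tibble.
#' @export
read_cohort <- function(path, features = NULL, id = NULL, kinds = NULL,
                        demographics = NULL, outcome = NULL,
                        impute = c("none", "mean_mode")) {
  impute <- match.arg(impute)
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(data) == 0L) abort(paste0("Empty cohort file: ", path))
  if (impute == "mean_mode") {
    target <- features %||%
      setdiff(names(data)[vapply(data, is.numeric, logical(1))],
              c(id, demographics, outcome))
    n_filled <- 0L
    for (col in target) {
      miss <- is.na(data[[col]])
      if (!any(miss)) next
      fill <- if (is.numeric(data[[col]])) {
        mean(data[[col]], na.rm = TRUE)
      } else {
        names(which.max(table(data[[col]])))
      }
      data[[col]][miss] <- fill
      n_filled <- n_filled + sum(miss)
    }
    if (n_filled > 0L) {
      rlang::inform(sprintf("Imputed %d missing feature value(s).", n_filled))
    }
  }
  as_cohort(data, features = features, id = id, kinds = kinds,
            demographics = demographics, outcome = outcome)
}

#' Write a chosen sample with its provenance
#'
#' Writes the selected row identifiers as a CSV (stable order) plus a JSON
#' sidecar (`<path>.json`) recording provenance: clustering method, k,
#' replicate, child seed and coverage metric value. Reading the CSV back
#' yields the same identifier set.
#'
#' @param selection A `covr_selection` from [select_optimal()] or
#'   [coverage_sample()].
#' @param cohort The cohort it was drawn from (source of row identifiers).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, cohort, path) {
  stopifnot(inherits(selection, "covr_selection"))
  idx <- selection$indices[[1]]
  ids <- cohort_ids(cohort)[idx]
  readr::write_csv(tibble::tibble(row = idx, id = ids), path)
  sidecar <- list(
    method = selection$method, k = selection$k,
    replicate = selection$replicate, seed = selection$seed,
    m = length(idx), metric = selection$metric
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
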