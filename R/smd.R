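#' Standardized mean difference between two samples
#'
#' Balance diagnostic for comparing the composition of two chart-review
#' samples. For a binary variable observed at proportions `prop_a` and
#' `prop_b`, the SMD is `|p_a - p_b| / sqrt((p_a(1-p_a) + p_b(1-p_b)) / 2)`.
#'
#' @param prop_a,prop_b Level prevalences in the two samples, in `[0, 1]`.
#' @return A non-negative scalar; 0 when the proportions agree.
#' @export
#' @examples
#' smd(0.47, 0.43) # 0.080 to three decimals
smd <- function(prop_a, prop_b) {
  if (any(c(prop_a, prop_b) < 0) || any(c(prop_a, prop_b) > 1)) {
    abort("Proportions must lie in [0, 1].")
  }
  denom <- sqrt((prop_a * (1 - prop_a) + prop_b * (1 - prop_b)) / 2)
  if (denom == 0) return(0)
  abs(prop_a - prop_b) / denom
}

#' @describeIn smd Multi-level (Mahalanobis) form for a categorical variable
#'   with `L` levels: the difference vector over the first `L - 1` level
#'   proportions is standardized by the average of the two multinomial
#'   covariance matrices. Reduces exactly to the binary form at `L = 2`. A
#'   singular covariance (e.g. a level absent from both samples) falls back
#'   to a pseudo-inverse with a warning.
#' @param props_a,props_b Full proportion vectors over the variable's levels,
#'   each summing to 1.
#' @export
smd_multilevel <- function(props_a, props_b) {
  if (length(props_a) != length(props_b)) {
    abort("Both samples must report the same levels.")
  }
  if (abs(sum(props_a) - 1) > 1e-6 || abs(sum(props_b) - 1) > 1e-6) {
    abort("Each proportion vector must sum to 1.")
  }
  L <- length(props_a)
  if (L < 2L) abort("Need at least two levels.")
  idx <- seq_len(L - 1L)
  d <- (props_a - props_b)[idx]
  cov_of <- function(p) diag(p[idx], L - 1L) - tcrossprod(p[idx])
  s <- (cov_of(props_a) + cov_of(props_b)) / 2
  s_inv <- tryCatch(solve(s), error = function(e) {
    warn("Degenerate level covariance; using a pseudo-inverse.")
    MASS::ginv(s)
  })
  sqrt(max(0, drop(t(d) %*% s_inv %*% d)))
}

#' Balance table for two samples
#'
#' Table of level prevalences and standardized mean differences comparing two
#' samples (e.g. a coverage sample vs a random sample) on a set of
#' categorical variables.
#'
#' @param data_a,data_b Data frames holding the two samples' rows.
#' @param variables Character vector of categorical column names to compare.
#' @return A tibble with one row per variable level: `variable`, `level`,
#'   `prop_a`, `prop_b`, and the per-variable `smd` (repeated across its
#'   levels).
#' @export
balance_table <- function(data_a, data_b, variables) {
  missing_cols <- setdiff(variables, intersect(names(data_a), names(data_b)))
  if (length(missing_cols)) {
    abort(paste0("Variables absent from a sample: ",
                 paste(missing_cols, collapse = ", ")))
  }
  purrr::map_dfr(variables, function(v) {
    lv <- sort(unique(c(as.character(data_a[[v]]), as.character(data_b[[v]]))))
    pa <- as.numeric(table(factor(data_a[[v]], levels = lv))) / nrow(data_a)
    pb <- as.numeric(table(factor(data_b[[v]], levels = lv))) / nrow(data_b)
    value <- if (length(lv) >= 2L) smd_multilevel(pa, pb) else 0
    tibble::tibble(variable = v, level = lv, prop_a = pa, prop_b = pb,
                   smd = value)
  })
}

#' Paired comparison of two sampling methods
#'
#' Paired t-test on per-dataset AUROC differences between two sampling
#' methods evaluated on the same simulated datasets.
#'
#' @param aurocs_a,aurocs_b Equal-length vectors of per-dataset AUROCs,
#'   paired by dataset.
#' @return A one-row tibble: `mean_diff` (a minus b), `statistic`, `df`,
#'   `p_value`, and `degenerate` (`TRUE` when the differences have zero
#'   variance, in which case the p-value is 1 for identical vectors and 0 for
#'   a constant nonzero shift).
#' @export
compare_methods <- function(aurocs_a, aurocs_b) {
  if (length(aurocs_a) != length(aurocs_b)) {
    abort("Paired AUROC vectors must have equal length.")
  }
  if (length(aurocs_a) < 2L) abort("Need at least two paired datasets.")
  d <- aurocs_a - aurocs_b
  if (sd(d) == 0) {
    return(tibble::tibble(
      mean_diff = mean(d), statistic = NA_real_,
      df = length(d) - 1L, p_value = if (mean(d) == 0) 1 else 0,
      degenerate = TRUE
    ))
  }
  tt <- t.test(aurocs_a, aurocs_b, paired = TRUE)
  tibble::tibble(mean_diff = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 degenerate = FALSE)
}
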