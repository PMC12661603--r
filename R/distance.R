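#' Distance settings for coverage computations
#'
#' Bundles the dissimilarity metric and the nearest-neighbor aggregation range
#' used by the coverage statistic. The default averages the 1st through 10th
#' nearest neighbor distances on standardized Euclidean features.
#'
#' @param metric One of `"euclidean"`, `"manhattan"`, `"gower"`. Gower is the
#'   supported route for mixed numeric/categorical features; the other two
#'   require all-numeric features.
#' @param standardize Z-score numeric features (using full-cohort mean and SD)
#'   before Euclidean/Manhattan distances. Ignored for Gower, which is
#'   range-normalized by construction. Clinical features usually carry
#'   heterogeneous units, so this defaults to `TRUE`.
#' @param n_lo,n_hi Aggregation range: the coverage score of a sample is the
#'   mean of the n-th nearest neighbor distances for `n = n_lo..n_hi`.
#'   Requires `n_lo <= n_hi` and `n_hi` no larger than any sample scored.
#'
#' @return A list of class `covr_dist_config`.
#' @export
#' @examples
#' dist_config(metric = "gower", n_lo = 1, n_hi = 1)
dist_config <- function(metric = c("euclidean", "manhattan", "gower"),
                        standardize = TRUE, n_lo = 1L, n_hi = 10L) {
  metric <- match.arg(metric)
  n_lo <- as.integer(n_lo); n_hi <- as.integer(n_hi)
  if (n_lo < 1L || n_hi < n_lo) abort("Need 1 <= n_lo <= n_hi.")
  structure(list(metric = metric, standardize = isTRUE(standardize),
                 n_lo = n_lo, n_hi = n_hi),
            class = "covr_dist_config")
}

# Prepare per-column encodings for a cohort under a config:
# z-scored numeric matrix for euclidean/manhattan, or the per-feature columns
# plus cohort-wide ranges for gower. Drops zero-variance/zero-range numeric
# columns with a warning (their contribution is undefined / identically zero).
prep_features <- function(cohort, cfg) {
  kinds <- cohort_kinds(cohort)
  feats <- cohort_features(cohort)
  if (cfg$metric %in% c("euclidean", "manhattan")) {
    if (any(kinds[feats] == "categorical")) {
      abort(paste0("Categorical features (",
                   paste(feats[kinds[feats] == "categorical"], collapse = ", "),
                   ") are not supported under the ", cfg$metric,
                   " metric; use metric = 'gower' or encode them explicitly."))
    }
    x <- feature_matrix(cohort)
    if (cfg$standardize) {
      mu <- colMeans(x)
      sdv <- apply(x, 2, sd)
      zero <- sdv == 0
      if (any(zero)) {
        warn(paste0("Dropping zero-variance feature(s) from standardized ",
                    "distance: ", paste(colnames(x)[zero], collapse = ", ")))
        x <- x[, !zero, drop = FALSE]
        mu <- mu[!zero]; sdv <- sdv[!zero]
      }
      if (ncol(x) == 0L) abort("No features left after dropping zero-variance columns.")
      x <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    }
    list(kind = "numeric", x = x)
  } else {
    cols <- lapply(feats, function(f) cohort[[f]])
    names(cols) <- feats
    ranges <- vapply(feats, function(f) {
      if (kinds[[f]] == "numeric") diff(range(cols[[f]])) else NA_real_
    }, numeric(1))
    zero <- !is.na(ranges) & ranges == 0
    if (any(zero)) {
      warn(paste0("Zero-range numeric feature(s) contribute 0 to Gower ",
                  "distance: ", paste(feats[zero], collapse = ", ")))
    }
    list(kind = "gower", cols = cols, kinds = kinds[feats], ranges = ranges)
  }
}

cross_dist_prepped <- function(prep, rows_a, rows_b) {
  if (prep$kind == "numeric") {
    a <- prep$x[rows_a, , drop = FALSE]
    b <- prep$x[rows_b, , drop = FALSE]
    d <- matrix(0, nrow(a), nrow(b))
    if (isTRUE(prep$manhattan)) {
      for (j in seq_len(ncol(a))) d <- d + abs(outer(a[, j], b[, j], "-"))
    } else {
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      d <- sqrt(pmax(d2, 0))
    }
    d
  } else {
    n_used <- 0L
    d <- matrix(0, length(rows_a), length(rows_b))
    for (f in names(prep$cols)) {
      col <- prep$cols[[f]]
      if (prep$kinds[[f]] == "numeric") {
        rng <- prep$ranges[[f]]
        if (!is.na(rng) && rng == 0) { n_used <- n_used + 1L; next }
        d <- d + abs(outer(col[rows_a], col[rows_b], "-")) / rng
      } else {
        d <- d + outer(col[rows_a], col[rows_b], "!=") * 1
      }
      n_used <- n_used + 1L
    }
    d / n_used
  }
}

#' Pairwise distances between two row sets of a cohort
#'
#' @param cohort A cohort data frame (see [as_cohort()]).
#' @param rows_a,rows_b Integer row positions; both default to all rows.
#' @param cfg A [dist_config()].
#' @return A `length(rows_a)` by `length(rows_b)` matrix of non-negative
#'   distances. Symmetric with a zero diagonal when `rows_a == rows_b`;
#'   Gower distances lie in `[0, 1]`.
#' @export
#' @examples
#' coh <- as_cohort(data.frame(x = c(0, 3), y = c(0, 4)))
#' pairwise_distance(coh, cfg = dist_config(standardize = FALSE))
pairwise_distance <- function(cohort, rows_a = seq_len(nrow(cohort)),
                              rows_b = seq_len(nrow(cohort)),
                              cfg = dist_config()) {
  cohort <- assert_cohort(cohort)
  check_rows(cohort, rows_a); check_rows(cohort, rows_b)
  prep <- prep_features(cohort, cfg)
  prep$manhattan <- cfg$metric == "manhattan"
  d <- cross_dist_prepped(prep, rows_a, rows_b)
  if (identical(rows_a, rows_b)) {
    # guard the self-distance identity against floating-point cancellation
    d <- (d + t(d)) / 2
    diag(d) <- 0
  }
  d
}

check_rows <- function(cohort, rows) {
  if (length(rows) == 0L) abort("Row index set must be non-empty.")
  if (anyNA(rows) || any(rows < 1L | rows > nrow(cohort))) {
    abort(sprintf("Row indices must lie in 1..%d.", nrow(cohort)))
  }
  if (anyDuplicated(rows)) abort("Row indices must be unique.")
  invisible(rows)
}

# shared core: totals of nth-nearest-sampled distances for n = 1..n_max
nn_totals <- function(cohort, sample, n_max, cfg) {
  cohort <- assert_cohort(cohort)
  sample <- as.integer(sample)
  check_rows(cohort, sample)
  if (n_max > length(sample)) {
    abort(sprintf("n (%d) cannot exceed the sample size (%d).",
                  n_max, length(sample)))
  }
  prep <- prep_features(cohort, cfg)
  prep$manhattan <- cfg$metric == "manhattan"
  nn_totals_prepped(prep, nrow(cohort), sample, n_max)
}

nn_totals_prepped <- function(prep, n_rows, sample, n_max) {
  if (prep$kind == "numeric") {
    .nn_totals_numeric(prep$x, as.integer(sample), as.integer(n_max),
                       isTRUE(prep$manhattan))
  } else {
    d <- cross_dist_prepped(prep, seq_len(n_rows), sample)
    .row_nsmallest_totals(d, as.integer(n_max))
  }
}

#' The nth nearest neighbor coverage distance
#'
#' The coverage of a candidate sample is measured by the sum, over every
#' member of the cohort (sampled members included, whose distance to
#' themselves is zero), of the distance from that member to the n-th nearest
#' member of the sample. Smaller totals mean every cohort member has a nearby
#' sampled representative.
#'
#' @inheritParams pairwise_distance
#' @param sample Integer row positions of the candidate sample.
#' @param n Which nearest sampled neighbor to use (`1 <= n <= length(sample)`).
#' @return A single non-negative number.
#' @export
#' @examples
#' coh <- as_cohort(data.frame(x = 0:3))
#' cfg <- dist_config(standardize = FALSE)
#' nth_nn_distance(coh, sample = c(1, 4), n = 1, cfg = cfg) # 2
nth_nn_distance <- function(cohort, sample, n, cfg = dist_config()) {
  n <- as.integer(n)
  if (n < 1L) abort("n must be a positive integer.")
  totals <- nn_totals(cohort, sample, n, cfg)
  totals[[n]]
}

#' @describeIn nth_nn_distance Mean of the nth nearest neighbor distances over
#'   `cfg$n_lo .. cfg$n_hi`; the default pool-scoring statistic.
#' @export
mean_nn_distance <- function(cohort, sample, cfg = dist_config()) {
  totals <- nn_totals(cohort, sample, cfg$n_hi, cfg)
  mean(totals[cfg$n_lo:cfg$n_hi])
}

#' @describeIn nth_nn_distance Full profile of the statistic for
#'   `n = 1..n_max`, as a tibble with columns `n` and `total_distance`
#'   (non-decreasing in `n`).
#' @param n_max Largest neighbor order to profile.
#' @export
nn_distance_profile <- function(cohort, sample, n_max = length(sample),
                                cfg = dist_config()) {
  totals <- nn_totals(cohort, sample, n_max, cfg)
  tibble::new_tibble(
    list(n = seq_len(n_max), total_distance = as.numeric(totals)),
    class = "covr_profile"
  )
}
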