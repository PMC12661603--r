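#' Generate the stratified sample pool
#'
#' Clusters the cohort over a grid of cluster counts and, for each k, draws
#' `reps` stratified candidate samples of size `m` with equal per-cluster
#' allocation. The pool is what [select_optimal()] searches for the candidate
#' with the best coverage. For hierarchical clustering one dendrogram is built
#' and re-cut at each k; k-means is refit per k. A master seed spawns one
#' child seed per (k, replicate) cell (k-major order), so any single draw can
#' be re-derived.
#'
#' @inheritParams pairwise_distance
#' @param m Candidate sample size.
#' @param k_grid Cluster counts to explore. Defaults to 2–5; larger structures
#'   (10+) tend to cover less effectively and are left to sensitivity runs.
#' @param reps Stratified draws per k (default 100).
#' @param method `"hierarchical"` or `"kmeans"`.
#' @param linkage Hierarchical linkage (see [fit_clusters()]).
#' @param seed Master seed; the pool is fully reproducible given it.
#' @return A tibble of class `covr_pool`, one row per candidate: `method`,
#'   `k`, `replicate`, `seed` (the child seed), `indices` (list-column of row
#'   positions) and `metric` (`NA` until scored).
#' @export
#' @examples
#' coh <- as_cohort(data.frame(x = rnorm(60), y = rnorm(60)))
#' pool <- generate_sample_pool(coh, m = 10, k_grid = 2:3, reps = 4, seed = 1)
#' nrow(pool) # 8
generate_sample_pool <- function(cohort, m, k_grid = 2:5, reps = 100L,
                                 method = c("hierarchical", "kmeans"),
                                 cfg = dist_config(), linkage = "ward.D2",
                                 seed = 1L) {
  cohort <- assert_cohort(cohort)
  method <- match.arg(method)
  m <- as.integer(m)
  k_grid <- as.integer(k_grid)
  reps <- as.integer(reps)
  if (m > nrow(cohort)) abort("m exceeds cohort size.")
  if (reps < 1L) abort("reps must be >= 1.")
  if (any(k_grid < 1L)) abort("k_grid values must be >= 1.")

  n_cells <- length(k_grid) * reps
  child <- derive_seeds(seed, n_cells + length(k_grid))
  kmeans_seeds <- child[n_cells + seq_along(k_grid)]
  tree <- if (method == "hierarchical") cluster_tree(cohort, cfg, linkage)
  models <- lapply(seq_along(k_grid), function(ki) {
    if (method == "hierarchical") {
      fit_clusters(cohort, k_grid[ki], "hierarchical", cfg, linkage,
                   tree = tree)
    } else {
      fit_clusters(cohort, k_grid[ki], "kmeans", cfg, seed = kmeans_seeds[ki])
    }
  })
  quotas <- lapply(models, function(cl) allocate_quota(cl$sizes, m))

  rows <- purrr::map2(
    rep(seq_along(k_grid), each = reps),
    rep(seq_len(reps), times = length(k_grid)),
    function(ki, r) {
      s <- child[(ki - 1L) * reps + r]
      idx <- stratified_sample(models[[ki]], quotas[[ki]], seed = s)
      tibble::tibble(method = method, k = k_grid[ki], replicate = r,
                     seed = s, indices = list(idx), metric = NA_real_)
    }
  )
  out <- dplyr::bind_rows(rows)
  class(out) <- c("covr_pool", class(out))
  out
}

#' Score every pool candidate with the coverage metric
#'
#' @param pool A pool tibble from [generate_sample_pool()] (any tibble with a
#'   list-column `indices` works).
#' @inheritParams pairwise_distance
#' @return The pool with `metric` filled: the mean nth nearest neighbor
#'   distance over `cfg$n_lo..cfg$n_hi` for each candidate.
#' @export
score_pool <- function(pool, cohort, cfg = dist_config()) {
  cohort <- assert_cohort(cohort)
  prep <- prep_features(cohort, cfg)
  prep$manhattan <- cfg$metric == "manhattan"
  pool$metric <- purrr::map_dbl(pool$indices, function(idx) {
    mean(nn_totals_prepped(prep, nrow(cohort), idx,
                           cfg$n_hi)[cfg$n_lo:cfg$n_hi])
  })
  pool
}

#' Pick the pool candidate with minimal coverage distance
#'
#' Scores every candidate (if not already scored) and returns the one with
#' the smallest mean nth nearest neighbor distance; ties go to the earliest
#' pool position, so selection is deterministic.
#'
#' @inheritParams score_pool
#' @return A one-row tibble of class `covr_selection` with the winning
#'   candidate's provenance (`method`, `k`, `replicate`, `seed`), `indices`
#'   and `metric`. The fully scored pool is attached as `attr(, "pool")`.
#' @export
select_optimal <- function(pool, cohort, cfg = dist_config()) {
  if (nrow(pool) == 0L) abort("The sample pool is empty.")
  if (anyNA(pool$metric)) pool <- score_pool(pool, cohort, cfg)
  best <- which.min(pool$metric)
  out <- pool[best, ]
  class(out) <- c("covr_selection", setdiff(class(out), "covr_pool"))
  attr(out, "pool") <- pool
  out
}

#' Coverage sampling, end to end
#'
#' The full procedure: cluster the cohort across `k_grid`, draw `reps`
#' equal-allocation stratified candidates per k, score each candidate by its
#' mean nth nearest neighbor distance to the whole cohort, and keep the
#' minimizer.
#'
#' @inheritParams generate_sample_pool
#' @return A `covr_selection` (see [select_optimal()]).
#' @export
#' @examples
#' coh <- as_cohort(data.frame(x = c(rnorm(50), rnorm(15, 6))))
#' sel <- coverage_sample(coh, m = 8, k_grid = 2:3, reps = 10, seed = 7)
#' sel$metric
coverage_sample <- function(cohort, m, k_grid = 2:5, reps = 100L,
                            method = c("hierarchical", "kmeans"),
                            cfg = dist_config(), linkage = "ward.D2",
                            seed = 1L) {
  pool <- generate_sample_pool(cohort, m, k_grid, reps, method, cfg,
                               linkage, seed)
  select_optimal(pool, cohort, cfg)
}

#' @export
print.covr_selection <- function(x, ...) {
  cat(sprintf(
    "<coverage selection> m = %d from %s clustering (k = %d, replicate %d)\n",
    length(x$indices[[1]]), x$method, x$k, x$replicate))
  cat(sprintf("  mean nn distance: %.4f\n", x$metric))
  invisible(x)
}
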