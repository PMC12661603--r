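# RNG scope guard: run code under a seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Child-seed scheme: a master seed deterministically spawns a sequence of
# 31-bit child seeds; entry t is re-derivable on its own.
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(2147483646L, n))
}

#' Cluster a cohort's feature space
#'
#' Fits the cluster structure from which stratified candidate samples are
#' drawn. Hierarchical clustering (the suggested method: its nested structure
#' matches the view of a cohort as patient subgroups) is deterministic given
#' the linkage and metric; k-means is deterministic given a seed.
#'
#' @inheritParams pairwise_distance
#' @param k Number of clusters, `1 <= k <= nrow(cohort)`.
#' @param method `"hierarchical"` (default) or `"kmeans"`.
#' @param linkage Hierarchical agglomeration rule passed to [stats::hclust()];
#'   Ward's method on (standardized) distances by default.
#' @param seed RNG seed for k-means initialization.
#' @param tree Optionally, a pre-computed dendrogram from [cluster_tree()];
#'   re-cutting one tree across a k-grid avoids refitting.
#' @return An object of class `covr_clusters`: a list with `labels` (integer
#'   cluster id per row, 1..k), `k`, `method`, `linkage`, `seed`, and `sizes`.
#' @export
#' @examples
#' coh <- as_cohort(data.frame(x = c(rnorm(10), rnorm(10, 8))))
#' fit_clusters(coh, k = 2)$sizes
fit_clusters <- function(cohort, k, method = c("hierarchical", "kmeans"),
                         cfg = dist_config(), linkage = "ward.D2",
                         seed = NULL, tree = NULL) {
  cohort <- assert_cohort(cohort)
  method <- match.arg(method)
  k <- as.integer(k)
  if (k < 1L || k > nrow(cohort)) {
    abort(sprintf("k must lie in 1..%d (cohort size).", nrow(cohort)))
  }
  if (method == "hierarchical") {
    if (is.null(tree)) tree <- cluster_tree(cohort, cfg, linkage)
    labels <- as.integer(cutree(tree, k = k))
    seed <- NULL
  } else {
    kinds <- cohort_kinds(cohort)
    if (any(kinds == "categorical")) {
      abort("k-means requires all-numeric features; use hierarchical with gower.")
    }
    prep <- prep_features(cohort, dist_config(metric = "euclidean",
                                              standardize = cfg$standardize))
    labels <- kmeans_labels(prep$x, k, seed %||% 1L)
  }
  new_clusters(labels, k, method,
               linkage = if (method == "hierarchical") linkage else NULL,
               seed = seed)
}

#' @describeIn fit_clusters Build the dendrogram once so a k-grid can re-cut
#'   it cheaply.
#' @export
cluster_tree <- function(cohort, cfg = dist_config(), linkage = "ward.D2") {
  cohort <- assert_cohort(cohort)
  prep <- prep_features(cohort, cfg)
  prep$manhattan <- cfg$metric == "manhattan"
  d <- if (prep$kind == "numeric" && !prep$manhattan) {
    dist(prep$x, method = "euclidean")
  } else if (prep$kind == "numeric") {
    dist(prep$x, method = "manhattan")
  } else {
    stats::as.dist(cross_dist_prepped(prep, seq_len(nrow(cohort)),
                                      seq_len(nrow(cohort))))
  }
  hclust(d, method = linkage)
}

#' @describeIn fit_clusters Wrap externally supplied labels (e.g. the true
#'   generating clusters of a simulated cohort) as a cluster model.
#' @param labels Integer-like vector of cluster memberships.
#' @export
cluster_model <- function(labels) {
  labels <- as.integer(as.factor(labels))
  new_clusters(labels, k = max(labels), method = "provided")
}

new_clusters <- function(labels, k, method, linkage = NULL, seed = NULL) {
  structure(
    list(labels = labels, k = as.integer(k), method = method,
         linkage = linkage, seed = seed,
         sizes = tabulate(labels, nbins = k)),
    class = "covr_clusters"
  )
}

#' @export
print.covr_clusters <- function(x, ...) {
  cat(sprintf("<covr_clusters> %s, k = %d, sizes: %s\n",
              x$method, x$k, paste(x$sizes, collapse = " ")))
  invisible(x)
}

# k-means with empty-cluster / degenerate-start recovery: retry with the next
# derived seed, at most 10 attempts.
kmeans_labels <- function(x, k, seed, attempts = 10L) {
  seeds <- derive_seeds(seed, attempts)
  for (s in seeds) {
    fit <- with_seed(s, tryCatch(
      kmeans(x, centers = k, nstart = 5L, iter.max = 50L),
      error = function(e) NULL
    ))
    if (!is.null(fit) && all(tabulate(fit$cluster, nbins = k) > 0L)) {
      return(as.integer(fit$cluster))
    }
  }
  abort(sprintf("k-means failed to produce %d non-empty clusters in %d attempts.",
                k, attempts))
}

#' Equal per-cluster sampling quotas
#'
#' Splits a chart-review budget evenly across clusters: `floor(m/k)` per
#' cluster with the remainder going one each to the largest clusters (ties to
#' the lowest cluster id). A cluster smaller than its quota contributes all
#' its members and the shortfall is redistributed over the remaining clusters
#' by the same rule. Reviewing 100 charts over 4 clusters therefore allocates
#' 25 to each.
#'
#' @param cluster_sizes Integer vector of cluster sizes.
#' @param m Total sample size; must not exceed `sum(cluster_sizes)`.
#' @return Integer vector of per-cluster quotas summing to `m`.
#' @export
#' @examples
#' allocate_quota(c(4000, 3000, 2000, 1000), 100) # 25 each
allocate_quota <- function(cluster_sizes, m) {
  cluster_sizes <- as.integer(cluster_sizes)
  m <- as.integer(m)
  if (any(cluster_sizes < 0L)) abort("Cluster sizes must be non-negative.")
  if (m > sum(cluster_sizes)) {
    abort(sprintf("Requested sample size %d exceeds cohort size %d.",
                  m, sum(cluster_sizes)))
  }
  k <- length(cluster_sizes)
  quota <- integer(k)
  active <- rep(TRUE, k)
  m_rem <- m
  repeat {
    ka <- sum(active)
    if (ka == 0L) break
    base <- m_rem %/% ka
    r <- m_rem %% ka
    q <- rep(base, ka)
    if (r > 0L) {
      ord <- order(-cluster_sizes[active], seq_len(ka))
      q[ord[seq_len(r)]] <- q[ord[seq_len(r)]] + 1L
    }
    over <- q > cluster_sizes[active]
    if (!any(over)) {
      quota[active] <- q
      break
    }
    capped <- which(active)[over]
    quota[capped] <- cluster_sizes[capped]
    m_rem <- m_rem - sum(cluster_sizes[capped])
    active[capped] <- FALSE
  }
  quota
}

#' Draw one stratified sample from a cluster model
#'
#' @param clusters A `covr_clusters` object (or raw label vector).
#' @param quota Per-cluster counts, e.g. from [allocate_quota()]; quotas must
#'   not exceed cluster sizes.
#' @param seed RNG seed for reproducibility.
#' @return Sorted integer vector of row positions, `sum(quota)` of them.
#' @export
stratified_sample <- function(clusters, quota, seed = NULL) {
  if (!inherits(clusters, "covr_clusters")) clusters <- cluster_model(clusters)
  quota <- as.integer(quota)
  if (length(quota) != clusters$k) {
    abort("quota must have one entry per cluster.")
  }
  if (any(quota > clusters$sizes)) {
    abort("Quota exceeds a cluster's size; use allocate_quota() first.")
  }
  with_seed(seed, {
    picks <- lapply(seq_len(clusters$k), function(j) {
      members <- which(clusters$labels == j)
      members[sample.int(length(members), quota[j])]
    })
    sort(unlist(picks))
  })
}

#' Baseline samplers
#'
#' `random_sample()` draws uniformly without replacement from the whole
#' cohort — the usual chart-review practice and the benchmark baseline.
#' `truth_sample()` stratifies on known generating cluster labels with equal
#' allocation (simulation-only oracle baseline).
#'
#' @param n Cohort size.
#' @param m Sample size, `m <= n`.
#' @param seed RNG seed.
#' @return Sorted integer vector of row positions.
#' @export
random_sample <- function(n, m, seed = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (m > n) abort(sprintf("Sample size %d exceeds cohort size %d.", m, n))
  with_seed(seed, sort(sample.int(n, m)))
}

#' @rdname random_sample
#' @param true_labels Generating cluster labels, one per cohort row.
#' @export
truth_sample <- function(true_labels, m, seed = NULL) {
  clusters <- cluster_model(true_labels)
  stratified_sample(clusters, allocate_quota(clusters$sizes, m), seed = seed)
}
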