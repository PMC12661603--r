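test_that("quota allocation splits the budget evenly with remainder and capping rules", {
  # the canonical worked example: 100 charts over 4 clusters
  expect_equal(allocate_quota(c(4000, 3000, 2000, 1000), 100),
               c(25, 25, 25, 25))
  # remainder goes to the largest clusters
  expect_equal(allocate_quota(c(40, 30, 20, 10), 10), c(3, 3, 2, 2))
  # a tiny cluster is exhausted and the shortfall redistributed
  expect_equal(allocate_quota(c(2, 98), 10), c(2, 8))
  # remainder ties broken by lowest cluster id
  expect_equal(allocate_quota(c(10, 10, 10), 4), c(2, 1, 1))
  expect_error(allocate_quota(c(3, 3), 10), "exceeds")
})

test_that("quota allocation is always feasible and exhaustive", {
  withr::local_seed(11)
  for (rep in 1:25) {
    sizes <- sample(1:50, sample(2:6, 1), replace = TRUE)
    m <- sample(seq_len(sum(sizes)), 1)
    q <- allocate_quota(sizes, m)
    expect_equal(sum(q), m)
    expect_true(all(q <= sizes))
    expect_true(all(q >= 0))
  }
})

test_that("stratified sampling respects quotas and is reproducible", {
  labels <- c(1, 1, 2, 2)
  idx <- stratified_sample(labels, c(1, 1), seed = 5)
  expect_length(idx, 2)
  expect_true(idx[1] %in% 1:2 && idx[2] %in% 3:4)
  # quota = cluster sizes returns everything
  expect_equal(stratified_sample(labels, c(2, 2), seed = 1), 1:4)
  expect_identical(stratified_sample(labels, c(1, 1), seed = 9),
                   stratified_sample(labels, c(1, 1), seed = 9))
  expect_error(stratified_sample(labels, c(3, 1), seed = 1), "exceeds")
})

test_that("clustering recovers well-separated blobs and handles edge k", {
  withr::local_seed(3)
  blobs <- as_cohort(data.frame(x = c(rnorm(20, -10), rnorm(20, 10)),
                                y = rnorm(40)))
  truth <- rep(1:2, each = 20)
  for (method in c("hierarchical", "kmeans")) {
    cl <- fit_clusters(blobs, 2, method, seed = 1)
    tab <- table(cl$labels, truth)
    # diagonal up to label permutation
    expect_equal(sort(diag(tab[order(tab[, 1], decreasing = TRUE), ])),
                 c(20, 20), ignore_attr = TRUE)
  }
  expect_equal(fit_clusters(blobs, 1)$labels, rep(1L, 40))
  expect_equal(sort(unique(fit_clusters(blobs, 40)$labels)), 1:40)
  expect_error(fit_clusters(blobs, 41), "k must lie")
})

test_that("k-means is deterministic under a seed and refuses categorical features", {
  coh <- random_cohort(40, p_num = 3, seed = 8)
  a <- fit_clusters(coh, 3, "kmeans", seed = 21)
  b <- fit_clusters(coh, 3, "kmeans", seed = 21)
  expect_identical(a$labels, b$labels)
  mixed <- random_cohort(20, p_num = 2, p_cat = 1, seed = 9)
  expect_error(fit_clusters(mixed, 2, "kmeans"), "numeric")
})

test_that("the sample pool has the promised shape, sizes and determinism", {
  coh <- random_cohort(60, p_num = 2, seed = 13)
  pool <- generate_sample_pool(coh, m = 10, k_grid = 2:3, reps = 5, seed = 99)
  expect_equal(nrow(pool), 10) # |k_grid| x reps
  expect_true(all(lengths(pool$indices) == 10))
  expect_true(all(!duplicated(pool[c("k", "replicate")])))
  pool2 <- generate_sample_pool(coh, m = 10, k_grid = 2:3, reps = 5, seed = 99)
  expect_identical(pool$indices, pool2$indices)
  # any single draw is re-derivable from its recorded child seed
  cl <- fit_clusters(coh, pool$k[4], "hierarchical")
  redraw <- stratified_sample(cl, allocate_quota(cl$sizes, 10),
                              seed = pool$seed[4])
  expect_identical(redraw, pool$indices[[4]])
})

test_that("select_optimal returns the pool argmin with first-wins ties", {
  coh <- as_cohort(data.frame(x = 0:3))
  cfg <- dist_config(standardize = FALSE, n_lo = 1, n_hi = 1)
  pool <- tibble::tibble(method = "provided", k = NA_integer_,
                         replicate = 1:2, seed = NA_integer_,
                         indices = list(c(1L, 2L), c(1L, 4L)),
                         metric = NA_real_)
  sel <- select_optimal(pool, coh, cfg)
  # brute force: sample {0,1} has total 1-NN distance 0+0+1+2 = 3; {0,3} has 2
  expect_identical(sel$indices[[1]], c(1L, 4L))
  expect_equal(sel$metric, 2)
  scored <- attr(sel, "pool")
  expect_equal(scored$metric, c(3, 2))
  expect_true(all(sel$metric <= scored$metric))

  # exact ties: earliest pool position wins
  tie_pool <- pool
  tie_pool$indices <- list(c(1L, 4L), c(1L, 4L))
  tie <- select_optimal(tie_pool, coh, cfg)
  expect_equal(tie$replicate, 1L)
  expect_error(select_optimal(pool[0, ], coh, cfg), "empty")
})

test_that("random and truth baselines honor their contracts", {
  expect_equal(random_sample(5, 5, seed = 1), 1:5)
  expect_identical(random_sample(100, 10, seed = 3),
                   random_sample(100, 10, seed = 3))
  expect_error(random_sample(5, 6), "exceeds")

  labels <- rep(1:4, each = 25)
  idx <- truth_sample(labels, 12, seed = 2)
  expect_equal(unname(table(labels[idx])), rep(3L, 4), ignore_attr = TRUE)
  # equal allocation regardless of cluster size (when feasible)
  skew <- rep(1:4, times = c(10, 30, 30, 30))
  idx2 <- truth_sample(skew, 12, seed = 2)
  expect_equal(unname(table(skew[idx2])), rep(3L, 4), ignore_attr = TRUE)
})

test_that("coverage samples hit allocation quotas on planted clusters and beat random", {
  withr::local_seed(17)
  # a small, internally heterogeneous minority cluster: the regime in which
  # evenly covering every cluster lowers the summed NN distance
  n_per <- c(12, 44, 44)
  centers <- c(-20, 0, 20)
  spread <- c(4, 1, 1)
  coh <- as_cohort(data.frame(
    x = rnorm(sum(n_per), rep(centers, n_per), rep(spread, n_per)),
    y = rnorm(sum(n_per), 0, rep(spread, n_per))))
  truth <- rep(1:3, n_per)
  cfg9 <- dist_config(n_hi = 3)
  sel <- coverage_sample(coh, m = 9, k_grid = 3, reps = 20, cfg = cfg9,
                         seed = 5)
  # equal allocation over the three planted clusters
  expect_equal(unname(table(truth[sel$indices[[1]]])), rep(3L, 3),
               ignore_attr = TRUE)
  # expected dominance of the coverage metric over random draws
  rand_metrics <- vapply(1:30, function(s) {
    mean_nn_distance(coh, random_sample(nrow(coh), 9, seed = s), cfg9)
  }, numeric(1))
  sel_metric <- mean_nn_distance(coh, sel$indices[[1]], cfg9)
  expect_lt(sel_metric, mean(rand_metrics))
})
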