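# Independent brute-force oracle for the coverage statistic: plain R loops
# over stats::dist() / cluster::daisy() distances, no shared code with the
# package's cross-distance or C++ kernels.

oracle_dist_matrix <- function(df, features, kinds, metric, standardize) {
  x <- as.data.frame(df)[, features, drop = FALSE]
  if (metric %in% c("euclidean", "manhattan")) {
    m <- as.matrix(x)
    if (standardize) m <- scale(m)
    as.matrix(stats::dist(m, method = metric))
  } else {
    for (f in features) {
      if (kinds[[f]] == "categorical") x[[f]] <- factor(x[[f]])
    }
    as.matrix(cluster::daisy(x, metric = "gower"))
  }
}

# nth nearest sampled distance summed over all cohort rows, by enumeration
oracle_nth_nn <- function(dmat, sample, n) {
  total <- 0
  for (i in seq_len(nrow(dmat))) {
    total <- total + unname(sort(dmat[i, sample])[n])
  }
  total
}

# random mixed-type cohort for property tests
random_cohort <- function(n, p_num, p_cat = 0, seed = 1) {
  withr::local_seed(seed)
  df <- as.data.frame(matrix(rnorm(n * p_num), n, p_num))
  names(df) <- paste0("num", seq_len(p_num))
  feats <- names(df)
  if (p_cat > 0) {
    for (j in seq_len(p_cat)) {
      df[[paste0("cat", j)]] <- sample(letters[1:3], n, replace = TRUE)
    }
    feats <- c(feats, paste0("cat", seq_len(p_cat)))
  }
  as_cohort(df, features = feats)
}

# pairwise AUROC by direct enumeration of case-control pairs
oracle_auroc <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}
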