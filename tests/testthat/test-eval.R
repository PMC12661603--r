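test_that("auroc matches worked examples and handles ties", {
  expect_equal(auroc(c(.9, .8, .2, .1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(.9, .6, .4, .1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "class")
})

test_that("auroc equals brute-force pair enumeration, ties included", {
  withr::local_seed(31)
  for (rep in 1:8) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    # coarse scores force ties
    scores <- round(runif(n), 1)
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("auroc agrees with an independent ROC implementation", {
  withr::local_seed(5)
  scores <- rnorm(150)
  labels <- rbinom(150, 1, plogis(scores))
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("bootstrap CIs behave: coverage of the estimate, determinism, width", {
  withr::local_seed(8)
  scores <- c(rnorm(60, 1), rnorm(90))
  labels <- rep(c(1, 0), c(60, 90))
  ci <- auroc_ci(scores, labels, n_boot = 500, seed = 3)
  point <- auroc(scores, labels)
  expect_lte(ci[["lo"]], point)
  expect_gte(ci[["hi"]], point)
  expect_identical(auroc_ci(scores, labels, n_boot = 500, seed = 3), ci)
  # perfect separation pins the upper bound at 1
  ps <- auroc_ci(c(2, 3, -2, -3), c(1, 1, 0, 0), n_boot = 200, seed = 1)
  expect_equal(ps[["hi"]], 1)
  # more data, narrower interval (averaged over seeds)
  widths <- vapply(1:10, function(s) {
    withr::local_seed(s)
    big_s <- rnorm(2000); big_y <- rbinom(2000, 1, plogis(big_s))
    small_s <- rnorm(100); small_y <- rbinom(100, 1, plogis(small_s))
    if (length(unique(small_y)) < 2) small_y[1:2] <- c(0, 1)
    big <- auroc_ci(big_s, big_y, n_boot = 200, seed = s)
    small <- auroc_ci(small_s, small_y, n_boot = 200, seed = s)
    (big[["hi"]] - big[["lo"]]) - (small[["hi"]] - small[["lo"]])
  }, numeric(1))
  expect_lt(mean(widths), 0)
})

test_that("subgroup AUROCs match filtered recomputation and flag single-class groups", {
  withr::local_seed(12)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, plogis(scores))
  groups <- rep(c("a", "b"), each = 100)
  tab <- subgroup_auroc(scores, labels, groups, ci = FALSE)
  expect_equal(tab$auroc[tab$group == "a"],
               auroc(scores[1:100], labels[1:100]))
  expect_equal(tab$auroc[tab$group == "b"],
               auroc(scores[101:200], labels[101:200]))
  # all rows in one group reduces to the overall AUROC
  one <- subgroup_auroc(scores, labels, rep("all", 200), ci = FALSE)
  expect_equal(one$auroc, auroc(scores, labels))
  # a controls-only group is reported, not an error
  labels2 <- labels; labels2[groups == "b"] <- 0
  tab2 <- subgroup_auroc(scores, labels2, groups, ci = FALSE)
  expect_false(tab2$evaluable[tab2$group == "b"])
  expect_true(is.na(tab2$auroc[tab2$group == "b"]))
})

test_that("an unpenalized phenotype fit recovers generating coefficients", {
  withr::local_seed(44)
  n <- 50000
  x <- matrix(rnorm(n * 3), n, 3)
  colnames(x) <- c("a", "b", "c")
  beta <- c(0.8, -0.4, 0)
  y <- rbinom(n, 1, plogis(-1 + x %*% beta))
  d <- data.frame(x, .outcome = y)
  fit <- fit_cp(d)
  est <- tidy(fit)
  for (j in 1:3) {
    row <- est[est$term == colnames(x)[j], ]
    expect_lt(abs(row$estimate - beta[j]) / row$std_error, 3)
  }
  expect_equal(glance(fit)$penalty, "none")
})

test_that("phenotype fitting is invariant to row order and scores via the inverse link", {
  withr::local_seed(9)
  d <- data.frame(x1 = rnorm(300), x2 = rnorm(300))
  d$.outcome <- rbinom(300, 1, plogis(d$x1 - d$x2))
  fit <- fit_cp(d)
  perm <- sample(300)
  fit_perm <- fit_cp(d[perm, ])
  expect_equal(coef_vec <- fit$coefficients, fit_perm$coefficients,
               tolerance = 1e-8)
  p <- predict(fit, d[1:5, ])
  lp <- predict(fit, d[1:5, ], type = "link")
  expect_equal(p, plogis(lp))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the lasso route shrinks and degenerates as the penalty grows", {
  withr::local_seed(10)
  d <- data.frame(x1 = rnorm(200), x2 = rnorm(200), x3 = rnorm(200))
  d$.outcome <- rbinom(200, 1, plogis(2 * d$x1))
  strong <- fit_cp(d, penalty = "l1", lambda = 5)
  expect_true(all(strong$coefficients == 0))
  expect_equal(length(unique(predict(strong, d))), 1) # constant score
  cv <- fit_cp(d, penalty = "l1", seed = 2)
  expect_gt(abs(cv$coefficients[["x1"]]), abs(cv$coefficients[["x3"]]))
  expect_identical(fit_cp(d, penalty = "l1", seed = 2)$lambda, cv$lambda)
})

test_that("single-class training samples are refused by name", {
  d <- data.frame(x1 = rnorm(20), .outcome = rep(1, 20))
  expect_error(fit_cp(d), "single class", class = "covr_single_class")
})

test_that("binary SMD reproduces the printed worked value and its identities", {
  expect_equal(round(smd(0.47, 0.43), 3), 0.080)
  expect_equal(smd(0.3, 0.3), 0)
  expect_equal(smd(0.6, 0.4), 0.2 / sqrt(0.24))
  expect_equal(smd(0.4, 0.6), smd(0.6, 0.4))
  expect_error(smd(1.2, 0.5), "\\[0, 1\\]")
})

test_that("multi-level SMD reduces to the binary form and matches published values", {
  expect_equal(smd_multilevel(c(0.47, 0.53), c(0.43, 0.57)), smd(0.47, 0.43))
  expect_equal(smd_multilevel(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  # four-level age comparison printed as 0.391 in the motivating study
  expect_equal(round(smd_multilevel(c(0.03, 0.24, 0.38, 0.35),
                                    c(0.02, 0.11, 0.38, 0.49)), 3), 0.391)
  expect_equal(round(smd_multilevel(c(0.48, 0.42, 0.04, 0.06),
                                    c(0.50, 0.35, 0.03, 0.12)), 3), 0.239)
  expect_error(smd_multilevel(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
})

test_that("balance tables report level proportions with one SMD per variable", {
  a <- data.frame(sex = rep(c("m", "f"), c(43, 57)),
                  age = rep(c("young", "old"), c(24, 76)))
  b <- data.frame(sex = rep(c("m", "f"), c(47, 53)),
                  age = rep(c("young", "old"), c(11, 89)))
  tab <- balance_table(a, b, c("sex", "age"))
  expect_equal(nrow(tab), 4)
  expect_equal(round(tab$smd[tab$variable == "sex"][1], 3), 0.080)
  sex_rows <- tab[tab$variable == "sex", ]
  expect_equal(sum(sex_rows$prop_a), 1)
  expect_equal(sum(sex_rows$prop_b), 1)
  expect_error(balance_table(a, b, "payer"), "payer")
})

test_that("the paired method comparison matches a hand-computed t-test", {
  a <- c(0.75, 0.74, 0.76, 0.75)
  b <- a - c(0.05, 0.04, 0.06, 0.05)
  cmp <- compare_methods(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / 2)
  expect_equal(cmp$statistic, t_hand)
  expect_equal(cmp$df, 3)
  expect_equal(cmp$p_value, 2 * stats::pt(-abs(t_hand), 3))
  # symmetry
  swapped <- compare_methods(b, a)
  expect_equal(swapped$mean_diff, -cmp$mean_diff)
  expect_equal(swapped$p_value, cmp$p_value)
  # degenerate zero-variance differences
  same <- compare_methods(a, a)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  shift <- compare_methods(a + 0.1, a)
  expect_true(shift$degenerate)
  expect_equal(shift$p_value, 0)
  expect_error(compare_methods(a, b[1:3]), "equal length")
})
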