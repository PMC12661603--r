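#' Benchmark sampling strategies on simulated cohorts
#'
#' The full simulation loop: for each of `n_datasets` cohorts drawn from the
#' scenario, draw one chart-review sample per method — hierarchical-cluster
#' coverage, k-means coverage, simple random, and truth-stratified (on the
#' generating labels) — fit an unpenalized logistic computable phenotype on
#' each sample, and evaluate it by AUROC on every unsampled row, overall and
#' within each true subgroup. Coverage of each sample is recorded as its mean
#' nth nearest neighbor distance.
#'
#' When the scenario has no subgroup structure (a single positive
#' proportion), the truth baseline is dropped: there is no structure to
#' stratify on.
#'
#' A sample whose outcome labels are single-class cannot train a phenotype;
#' such a draw is retried with the next derived seed (at most 5 attempts,
#' counted in the report). At typical event rates this is essentially never
#' triggered.
#'
#' @param scenario A [make_scenario()] object.
#' @param outcome_model A [default_outcome_model()] object, or `NULL` to
#'   build the default for the scenario.
#' @param n_datasets Number of simulated cohorts.
#' @param m Chart-review sample size per dataset.
#' @param methods Subset of `c("hierarchical", "kmeans", "random", "truth")`.
#' @param k_grid,reps Pool settings for the coverage methods (see
#'   [generate_sample_pool()]).
#' @param cfg Distance settings ([dist_config()]); also sets the
#'   nearest-neighbor averaging range of the reported coverage distances.
#' @param seed Master seed; every dataset, draw and redraw derives from it.
#' @return An object of class `covr_benchmark`: a list with `results` (a long
#'   tibble: `dataset`, `method`, `group` — `"overall"` or a subgroup id —
#'   `auroc`, `n_test`, and for overall rows the coverage `distance`),
#'   the scenario, the outcome model and run settings. Use [tidy()] for the
#'   per-method summary, [glance()] for the headline coverage-vs-random
#'   contrast, and [autoplot()] to visualize.
#' @export
#' @examples
#' \donttest{
#' sc <- make_scenario(2, n = 600, p = 10, seed = 1)
#' bm <- run_benchmark(sc, n_datasets = 3, m = 60, reps = 10, seed = 1)
#' tidy(bm)
#' }
run_benchmark <- function(scenario, outcome_model = NULL, n_datasets = 50L,
                          m = 120L,
                          methods = c("hierarchical", "kmeans", "random",
                                      "truth"),
                          k_grid = 2:5, reps = 100L, cfg = dist_config(),
                          seed = 1L) {
  stopifnot(inherits(scenario, "covr_scenario"))
  methods <- match.arg(methods, several.ok = TRUE)
  n_datasets <- as.integer(n_datasets)
  if (n_datasets < 2L) abort("n_datasets must be at least 2.")
  if (m > scenario$n) abort("m exceeds the scenario cohort size.")
  if (sum(scenario$proportions > 0) < 2L && "truth" %in% methods) {
    methods <- setdiff(methods, "truth")
  }
  master <- derive_seeds(seed, n_datasets + 1L)
  if (is.null(outcome_model)) {
    outcome_model <- default_outcome_model(scenario, seed = master[n_datasets + 1L])
  }

  n_redraws <- 0L
  per_dataset <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    sub <- derive_seeds(master[d], 2L + 5L * length(methods))
    sim <- simulate_cohort(scenario, seed = sub[1L])
    sim <- simulate_outcomes(sim, outcome_model, seed = sub[2L])

    rows <- list()
    for (mi in seq_along(methods)) {
      meth <- methods[mi]
      draw_seeds <- sub[2L + (mi - 1L) * 5L + 1:5]
      res <- NULL
      for (attempt in seq_along(draw_seeds)) {
        s <- draw_seeds[attempt]
        cand <- switch(
          meth,
          hierarchical = ,
          kmeans = {
            sel <- coverage_sample(sim, m, k_grid = k_grid, reps = reps,
                                   method = meth, cfg = cfg, seed = s)
            list(idx = sel$indices[[1]], distance = sel$metric)
          },
          random = {
            idx <- random_sample(nrow(sim), m, seed = s)
            list(idx = idx, distance = mean_nn_distance(sim, idx, cfg))
          },
          truth = {
            idx <- truth_sample(sim$.cluster, m, seed = s)
            list(idx = idx, distance = mean_nn_distance(sim, idx, cfg))
          }
        )
        if (length(unique(sim$.outcome[cand$idx])) == 2L) {
          res <- cand
          break
        }
        n_redraws <- n_redraws + 1L
      }
      if (is.null(res)) {
        warn(sprintf("Dataset %d, method %s: single-class sample after %d draws; skipped.",
                     d, meth, length(draw_seeds)))
        next
      }
      fit <- fit_cp(sim[res$idx, ], outcome = ".outcome",
                    features = cohort_features(sim), penalty = "none")
      test <- setdiff(seq_len(nrow(sim)), res$idx)
      scores <- predict(fit, sim[test, ])
      y <- sim$.outcome[test]
      sub_tbl <- subgroup_auroc(scores, y, groups = sim$.cluster[test],
                                ci = FALSE)
      rows[[meth]] <- dplyr::bind_rows(
        tibble::tibble(dataset = d, method = meth, group = "overall",
                       auroc = auroc(scores, y), n_test = length(test),
                       distance = res$distance),
        tibble::tibble(dataset = d, method = meth,
                       group = paste0("cluster_", sub_tbl$group),
                       auroc = sub_tbl$auroc, n_test = sub_tbl$n,
                       distance = NA_real_)
      )
    }
    per_dataset[[d]] <- dplyr::bind_rows(rows)
  }
  structure(
    list(results = dplyr::bind_rows(per_dataset), scenario = scenario,
         outcome_model = outcome_model,
         settings = list(n_datasets = n_datasets, m = m, methods = methods,
                         k_grid = k_grid, reps = reps, cfg = cfg,
                         seed = seed),
         n_redraws = n_redraws),
    class = "covr_benchmark"
  )
}

#' @export
print.covr_benchmark <- function(x, ...) {
  cat(sprintf("<benchmark> scenario set %s, %d datasets, m = %d\n",
              x$scenario$set_id, x$settings$n_datasets, x$settings$m))
  print(tidy(x))
  invisible(x)
}

#' Summarize a sampling benchmark
#'
#' `tidy()` aggregates a [run_benchmark()] result across datasets: per method
#' and group, the mean AUROC with an across-dataset 95% normal CI, the mean
#' coverage distance (overall rows), and for non-random methods the paired
#' t-test p-value of the AUROC difference against the random baseline on the
#' same datasets. `glance()` reduces to the headline contrast: the mean
#' overall AUROC gain of hierarchical coverage over random and its paired
#' p-value.
#'
#' @param x A `covr_benchmark`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.covr_benchmark <- function(x, ...) {
  res <- x$results
  summ <- res |>
    dplyr::group_by(.data$method, .data$group) |>
    dplyr::summarise(
      n_datasets = dplyr::n(),
      mean_auroc = mean(.data$auroc, na.rm = TRUE),
      se = sd(.data$auroc, na.rm = TRUE) / sqrt(sum(!is.na(.data$auroc))),
      mean_distance = mean(.data$distance, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(ci_lo = .data$mean_auroc - qnorm(0.975) * .data$se,
                  ci_hi = .data$mean_auroc + qnorm(0.975) * .data$se,
                  se = NULL) |>
    dplyr::relocate("ci_lo", "ci_hi", .after = "mean_auroc")
  if ("random" %in% res$method) {
    pvals <- purrr::map_dfr(
      setdiff(unique(res$method), "random"),
      function(meth) {
        purrr::map_dfr(unique(res$group), function(g) {
          a <- dplyr::filter(res, .data$method == meth, .data$group == g,
                             !is.na(.data$auroc))
          b <- dplyr::filter(res, .data$method == "random", .data$group == g,
                             !is.na(.data$auroc))
          shared <- intersect(a$dataset, b$dataset)
          if (length(shared) < 2L) {
            return(tibble::tibble(method = meth, group = g,
                                  p_vs_random = NA_real_))
          }
          cmp <- compare_methods(a$auroc[match(shared, a$dataset)],
                                 b$auroc[match(shared, b$dataset)])
          tibble::tibble(method = meth, group = g, p_vs_random = cmp$p_value)
        })
      }
    )
    summ <- dplyr::left_join(summ, pvals, by = c("method", "group"))
  }
  dplyr::arrange(summ, .data$group != "overall", .data$group, .data$method)
}

#' @rdname tidy.covr_benchmark
#' @export
glance.covr_benchmark <- function(x, ...) {
  res <- dplyr::filter(x$results, .data$group == "overall")
  ref_method <- if ("hierarchical" %in% res$method) "hierarchical" else
    setdiff(unique(res$method), "random")[1]
  a <- dplyr::filter(res, .data$method == ref_method)
  b <- dplyr::filter(res, .data$method == "random")
  shared <- intersect(a$dataset, b$dataset)
  cmp <- compare_methods(a$auroc[match(shared, a$dataset)],
                         b$auroc[match(shared, b$dataset)])
  tibble::tibble(
    scenario = x$scenario$set_id,
    n_datasets = x$settings$n_datasets,
    m = x$settings$m,
    coverage_method = ref_method,
    auroc_gain = cmp$mean_diff,
    p_value = cmp$p_value,
    distance_ratio = mean(a$distance) / mean(b$distance),
    n_redraws = x$n_redraws
  )
}
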