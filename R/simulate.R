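#' Scenario specifications for clustered-cohort simulation
#'
#' Builds the generative settings for a simulated patient cohort: a mixture of
#' k = 4 latent subgroups at one of five preset proportion profiles, each
#' subgroup with its own feature centroid, plus correlated, heavy-ish-tailed
#' noise. Features follow `X = B[cluster, ] + e` where `B` is the k x p
#' centroid matrix and each row of `e` is a single-factor Gaussian vector
#' (`sqrt(rho) * f + sqrt(1 - rho) * eps`, correlation `rho` between any two
#' features) scaled by a two-component mixture draw. Clinical features move
#' together (severity-like common factor), so the cohort's effective
#' dimensionality is low even at p = 10.
#'
#' The preset profiles are: set 0 — `(1, 0, 0, 0)` (no subgroup structure);
#' set 1 — `(0.25, 0.25, 0.25, 0.25)` (equal subgroups); set 2 —
#' `(0.1, 0.3, 0.3, 0.3)` (one minority subgroup); set 3 —
#' `(0.1, 0.1, 0.4, 0.4)` (two minorities); set 4 — `(0.1, 0.1, 0.1, 0.7)`
#' (one dominant group).
#'
#' Minority subgroups (mixture proportion at or below `minority_threshold`)
#' are given `minority_dispersion` times the within-cluster noise scale:
#' rarer presentations are modelled as internally more heterogeneous, which
#' is also what makes equal per-cluster allocation genuinely optimal for the
#' coverage distance rather than a matter of taste.
#'
#' Centroids are drawn once per scenario seed from a spherical Gaussian and
#' rescaled so the mean between-centroid distance is `separation` times the
#' per-coordinate noise SD of a majority cluster.
#'
#' @param set_id Which proportion profile, 0–4.
#' @param n Cohort size per simulated dataset.
#' @param p Number of clinical features.
#' @param seed Seed for the centroid draw (part of the scenario, so every
#'   dataset simulated from it shares the same subgroup geometry).
#' @param separation Mean between-centroid distance in units of the majority
#'   per-coordinate noise SD.
#' @param factor_cor Correlation `rho` between any two features induced by
#'   the common severity factor.
#' @param noise_weights,noise_scales Mixture weights and component scale
#'   multipliers of the row-level noise mixture.
#' @param minority_threshold Proportion at or below which a subgroup counts
#'   as a minority.
#' @param minority_dispersion Noise-scale multiplier for minority subgroups.
#' @return A list of class `covr_scenario`; `dispersion` holds the realized
#'   per-cluster scale multipliers.
#' @export
#' @examples
#' make_scenario(2, n = 1000)$proportions # 0.1 0.3 0.3 0.3
make_scenario <- function(set_id, n = 10000L, p = 10L, seed = 1L,
                          separation = 12, factor_cor = 0.9,
                          noise_weights = c(0.9, 0.1),
                          noise_scales = c(1, 2),
                          minority_threshold = 0.1,
                          minority_dispersion = 2) {
  profiles <- list(
    `0` = c(1.0, 0, 0, 0),
    `1` = c(0.25, 0.25, 0.25, 0.25),
    `2` = c(0.1, 0.3, 0.3, 0.3),
    `3` = c(0.1, 0.1, 0.4, 0.4),
    `4` = c(0.1, 0.1, 0.1, 0.7)
  )
  key <- as.character(set_id)
  if (!key %in% names(profiles)) {
    abort("set_id must be one of 0, 1, 2, 3, 4.")
  }
  if (factor_cor < 0 || factor_cor >= 1) abort("factor_cor must lie in [0, 1).")
  proportions <- profiles[[key]]
  k <- length(proportions)
  noise_weights <- noise_weights / sum(noise_weights)
  noise_sd <- sqrt(sum(noise_weights * noise_scales^2))
  dispersion <- ifelse(proportions > 0 & proportions <= minority_threshold,
                       minority_dispersion, 1)
  b <- with_seed(seed, matrix(rnorm(k * p), k, p))
  b <- b * (separation * noise_sd / mean(dist(b)))
  structure(
    list(set_id = set_id, n = as.integer(n), p = as.integer(p), k = k,
         proportions = proportions, B = b, factor_cor = factor_cor,
         noise_weights = noise_weights, noise_scales = noise_scales,
         noise_sd = noise_sd, dispersion = dispersion, seed = seed),
    class = "covr_scenario"
  )
}

#' @export
print.covr_scenario <- function(x, ...) {
  cat(sprintf("<scenario set %s> n = %d, p = %d, proportions: %s\n",
              x$set_id, x$n, x$p, paste(x$proportions, collapse = "/")))
  invisible(x)
}

#' Simulate a clustered cohort from a scenario
#'
#' Assigns each row a subgroup label (independent multinomial draws at the
#' scenario proportions), then sets its features to the subgroup centroid
#' plus a correlated noise vector: a shared severity factor across features
#' (`factor_cor`), an idiosyncratic part, a row-level mixture scale (heavy-ish
#' tails), and the subgroup's dispersion multiplier.
#'
#' @param scenario A [make_scenario()] object.
#' @param seed Seed for this realization (labels and noise).
#' @return A cohort tibble (see [as_cohort()]) with columns `.id`, `.cluster`
#'   and features `x1..xp`; `.cluster` is metadata, not a feature.
#' @export
#' @examples
#' sim <- simulate_cohort(make_scenario(1, n = 200), seed = 3)
#' table(sim$.cluster)
simulate_cohort <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "covr_scenario"))
  n <- scenario$n; p <- scenario$p; k <- scenario$k
  rho <- scenario$factor_cor
  with_seed(seed, {
    labels <- sample.int(k, n, replace = TRUE, prob = scenario$proportions)
    s <- scenario$noise_scales[
      sample.int(length(scenario$noise_weights), n, replace = TRUE,
                 prob = scenario$noise_weights)]
    s <- s * scenario$dispersion[labels]
    f <- rnorm(n)
    eps <- matrix(rnorm(n * p), n, p)
    e <- (sqrt(rho) * f + sqrt(1 - rho) * eps) * s
    x <- scenario$B[labels, , drop = FALSE] + e
    colnames(x) <- paste0("x", seq_len(p))
    out <- tibble::as_tibble(as.data.frame(x))
    out <- dplyr::mutate(out, .id = dplyr::row_number(),
                         .cluster = labels, .before = 1L)
    coh <- as_cohort(out, features = colnames(x), id = ".id")
    attr(coh, "scenario") <- scenario
    coh
  })
}

#' Default phenotype outcome model for simulated cohorts
#'
#' Binary outcomes follow a logistic model on the subgroup indicators and the
#' features: `logit P(y = 1) = alpha0 + alpha[cluster] + X %*% beta`. To mimic
#' real phenotyping tasks only the first half of the features carry signal
#' (alternating coefficients `+beta_mag`/`-beta_mag`); the rest are noise with
#' respect to the outcome. Subgroup effects start from the pattern
#' `(0, +0.5, -0.5, +1.0)` (subgroup 1 as reference) and every minority
#' subgroup additionally receives `minority_effect` on the logit scale. This
#' encodes the atypical-presentation situation that motivates coverage
#' sampling: a rare subgroup whose clinical features read as ordinary but
#' whose true event risk is sharply elevated, so a phenotype trained without
#' seeing that subgroup misranks it. The intercept is calibrated by a 1-D
#' root search so the marginal event rate on a reference cohort simulated
#' from the scenario is `target_rate`.
#'
#' @param scenario A [make_scenario()] object.
#' @param beta_mag Absolute value of the nonzero feature coefficients.
#' @param minority_effect Additional logit effect for minority subgroups.
#' @param target_rate Marginal event probability to calibrate the intercept
#'   to (default 0.3, a typical phenotype prevalence within a screened
#'   cohort).
#' @param calib_n Rows in the calibration cohort for the intercept search.
#' @param seed Seed for the calibration draw.
#' @return A list of class `covr_outcome_model` with `alpha0`, `alpha`
#'   (length k), `beta` (length p) and `signal` (indices of nonzero
#'   coefficients).
#' @export
#' @examples
#' m <- default_outcome_model(make_scenario(2, n = 500))
#' sum(m$beta != 0) # half the features
default_outcome_model <- function(scenario, beta_mag = 0.3,
                                  minority_effect = 4, target_rate = 0.3,
                                  calib_n = 20000L, seed = 1L) {
  stopifnot(inherits(scenario, "covr_scenario"))
  k <- scenario$k; p <- scenario$p
  n_signal <- p %/% 2L
  beta <- numeric(p)
  if (n_signal > 0L) {
    beta[seq_len(n_signal)] <- beta_mag * (-1)^(seq_len(n_signal) + 1L)
  }
  alpha <- c(0, 0.5, -0.5, 1.0)[((seq_len(k) - 1L) %% 4L) + 1L]
  alpha[1L] <- 0
  minority <- scenario$dispersion > 1
  alpha[minority] <- alpha[minority] + minority_effect

  calib <- scenario
  calib$n <- as.integer(calib_n)
  ref <- simulate_cohort(calib, seed = seed)
  z <- alpha[ref$.cluster] + drop(feature_matrix(ref) %*% beta)
  alpha0 <- uniroot(function(a0) mean(plogis(a0 + z)) - target_rate,
                    interval = c(-30, 30))$root
  structure(
    list(alpha0 = alpha0, alpha = alpha, beta = beta,
         signal = which(beta != 0), target_rate = target_rate),
    class = "covr_outcome_model"
  )
}

#' Event probabilities under an outcome model
#'
#' @param cohort A simulated cohort with a `.cluster` column.
#' @param model A `covr_outcome_model`.
#' @return Per-row event probabilities on the probability scale.
#' @export
outcome_probability <- function(cohort, model) {
  stopifnot(inherits(model, "covr_outcome_model"))
  if (!".cluster" %in% names(cohort)) abort("Cohort lacks a .cluster column.")
  x <- feature_matrix(cohort)
  if (ncol(x) != length(model$beta)) {
    abort(sprintf("Model has %d feature effects but cohort has %d features.",
                  length(model$beta), ncol(x)))
  }
  if (max(cohort$.cluster) > length(model$alpha)) {
    abort("Cohort has more clusters than the outcome model.")
  }
  plogis(model$alpha0 + model$alpha[cohort$.cluster] + drop(x %*% model$beta))
}

#' Draw binary phenotype outcomes
#'
#' Adds an `.outcome` column of independent Bernoulli draws at the logistic
#' probabilities of the outcome model.
#'
#' @inheritParams outcome_probability
#' @param seed Seed for the Bernoulli draws.
#' @return The cohort tibble with a binary `.outcome` column appended.
#' @export
simulate_outcomes <- function(cohort, model, seed = 1L) {
  pr <- outcome_probability(cohort, model)
  cohort$.outcome <- with_seed(seed, rbinom(length(pr), 1L, pr))
  cohort
}
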