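#' Fit a probabilistic computable phenotype
#'
#' Logistic regression of a binary chart-review label on the clinical
#' features, either unpenalized (maximum likelihood, the simulation default)
#' or lasso-penalized (`penalty = "l1"`, the workflow used on real cohorts
#' with many features). Scores are produced on the probability scale through
#' the logistic inverse link.
#'
#' @param data A data frame of training rows (typically the reviewed sample).
#' @param outcome Name of the binary outcome column (default `".outcome"`).
#' @param features Feature column names; defaults to the cohort's declared
#'   features when `data` is a cohort, otherwise all numeric non-role columns.
#' @param penalty `"none"` or `"l1"`.
#' @param lambda Lasso penalty strength. `NULL` selects it by 10-fold
#'   cross-validation with a deterministic fold assignment derived from
#'   `seed`.
#' @param seed Seed for the cross-validation folds.
#' @return An object of class `covr_cp` with the intercept, named coefficient
#'   vector, penalty settings and training size. Supports [predict()],
#'   [tidy()] and [glance()].
#' @export
#' @examples
#' d <- data.frame(x1 = rnorm(200))
#' d$.outcome <- rbinom(200, 1, plogis(2 * d$x1))
#' fit <- fit_cp(d)
#' glance(fit)
fit_cp <- function(data, outcome = ".outcome", features = NULL,
                   penalty = c("none", "l1"), lambda = NULL, seed = 1L) {
  penalty <- match.arg(penalty)
  if (is.null(features)) {
    features <- if (inherits(data, "covr_cohort")) {
      cohort_features(data)
    } else {
      setdiff(names(data)[vapply(data, is.numeric, logical(1))], outcome)
    }
  }
  if (!outcome %in% names(data)) {
    abort(paste0("Outcome column '", outcome, "' not found."))
  }
  y <- data[[outcome]]
  if (anyNA(y) || !all(y %in% c(0, 1))) abort("Outcome must be binary 0/1.")
  if (all(y == y[1])) {
    abort(sprintf("Training outcome has a single class (all %s).", y[1]),
          class = "covr_single_class")
  }
  x <- as.matrix(as.data.frame(data)[, features, drop = FALSE])
  storage.mode(x) <- "double"

  if (penalty == "none") {
    df <- data.frame(.y = y, x)
    # quasi-separated small samples are allowed to run their IRLS path out;
    # extreme but finite fits are kept, true non-convergence errors below
    fit <- suppressWarnings(
      glm(.y ~ ., data = df, family = binomial(),
          control = stats::glm.control(maxit = 100L)))
    if (!fit$converged) {
      abort(sprintf("Logistic fit did not converge in %d iterations.", fit$iter))
    }
    cf <- coef(fit)
    intercept <- cf[[1]]
    beta <- setNames(as.numeric(cf[-1]), features)
    vc <- summary(fit)$coefficients
    se <- setNames(vc[, "Std. Error"], rownames(vc))
    lambda_used <- NA_real_
  } else {
    if (is.null(lambda)) {
      foldid <- with_seed(seed, sample(rep_len(1:10, length(y))))
      cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                              foldid = foldid)
      lambda_used <- cv$lambda.min
      fit <- cv$glmnet.fit
    } else {
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                            lambda = lambda)
      lambda_used <- lambda
    }
    cf <- coef(fit, s = lambda_used)
    intercept <- cf[1, 1]
    beta <- setNames(as.numeric(cf[-1, 1]), features)
    se <- NULL
  }
  structure(
    list(intercept = intercept, coefficients = beta, std_errors = se,
         penalty = penalty, lambda = lambda_used, features = features,
         n_train = length(y), n_case = sum(y == 1)),
    class = "covr_cp"
  )
}

#' @export
predict.covr_cp <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  x <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  lp <- object$intercept + drop(x %*% object$coefficients)
  if (type == "response") plogis(lp) else lp
}

#' @export
print.covr_cp <- function(x, ...) {
  cat(sprintf("<computable phenotype> %s logistic, %d features, n = %d (%d cases)\n",
              if (x$penalty == "l1") "lasso" else "unpenalized",
              length(x$coefficients), x$n_train, x$n_case))
  invisible(x)
}

#' @export
tidy.covr_cp <- function(x, ...) {
  out <- tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
  if (!is.null(x$std_errors)) out$std_error <- unname(x$std_errors[out$term])
  out
}

#' @export
glance.covr_cp <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train, n_case = x$n_case, penalty = x$penalty,
    lambda = x$lambda, n_nonzero = sum(x$coefficients != 0)
  )
}

#' Area under the ROC curve
#'
#' Mann–Whitney form: the probability that a randomly chosen case outscores a
#' randomly chosen control, with ties counted one half. Computed from
#' midranks, so exact under ties.
#'
#' @param scores Numeric predicted scores.
#' @param labels Binary 0/1 outcome labels.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(.9, .6, .4, .1), c(1, 0, 1, 0)) # 0.75
auroc <- function(scores, labels) {
  check_binary(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_binary <- function(labels) {
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    abort("Labels must be binary 0/1 without missing values.")
  }
  if (length(unique(labels)) < 2L) {
    abort(sprintf("Both outcome classes are required (only class %s present).",
                  labels[1]), class = "covr_single_class")
  }
}

#' Bootstrap confidence interval for AUROC
#'
#' Percentile interval over stratified resamples: cases and controls are
#' resampled separately so every replicate retains both classes.
#'
#' @inheritParams auroc
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param level Confidence level.
#' @param seed RNG seed.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
auroc_ci <- function(scores, labels, n_boot = 1000L, level = 0.95, seed = 1L) {
  check_binary(labels)
  if (n_boot < 100L) abort("n_boot must be at least 100.")
  case <- which(labels == 1)
  ctrl <- which(labels == 0)
  stats <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- c(case[sample.int(length(case), replace = TRUE)],
           ctrl[sample.int(length(ctrl), replace = TRUE)])
    auroc(scores[i], labels[i])
  }, numeric(1)))
  a <- (1 - level) / 2
  q <- quantile(stats, c(a, 1 - a), names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' AUROC within subgroups
#'
#' Evaluates the phenotype's discrimination separately in each subgroup of
#' the test data. Groups whose test rows contain a single outcome class are
#' reported as not evaluable (`auroc = NA`) rather than erroring, matching
#' how tiny demographic strata are reported in practice.
#'
#' @inheritParams auroc_ci
#' @param groups Subgroup label per row (factor-like).
#' @param ci Whether to attach bootstrap CIs per group.
#' @return A tibble with one row per group: `group`, `n`, `n_case`,
#'   `auroc`, optional `ci_lo`/`ci_hi`, and `evaluable`.
#' @export
subgroup_auroc <- function(scores, labels, groups, ci = TRUE,
                           n_boot = 1000L, level = 0.95, seed = 1L) {
  if (length(groups) != length(scores)) {
    abort("groups must label every test row.")
  }
  lv <- sort(unique(groups))
  seeds <- derive_seeds(seed, length(lv))
  purrr::map2_dfr(lv, seeds, function(g, s) {
    sel <- groups == g
    y <- labels[sel]
    ok <- length(unique(y)) == 2L
    row <- tibble::tibble(group = g, n = sum(sel), n_case = sum(y == 1),
                          auroc = if (ok) auroc(scores[sel], y) else NA_real_,
                          evaluable = ok)
    if (ci) {
      bounds <- if (ok) {
        auroc_ci(scores[sel], y, n_boot = n_boot, level = level, seed = s)
      } else {
        c(lo = NA_real_, hi = NA_real_)
      }
      row$ci_lo <- bounds[["lo"]]; row$ci_hi <- bounds[["hi"]]
      row <- row[, c("group", "n", "n_case", "auroc", "ci_lo", "ci_hi",
                     "evaluable")]
    }
    row
  })
}
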