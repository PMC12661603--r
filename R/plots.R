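#' Plot a nearest-neighbor distance profile
#'
#' Total nth nearest neighbor distance against n; flatter, lower curves mean
#' a sample whose members blanket the cohort. Supply several samples'
#' profiles bound together with a `sample` column to compare methods.
#'
#' @param object A profile tibble from [nn_distance_profile()] (optionally
#'   with an extra grouping column `sample`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.covr_profile <- function(object, ...) {
  mapping <- if ("sample" %in% names(object)) {
    ggplot2::aes(x = .data$n, y = .data$total_distance,
                 colour = .data$sample)
  } else {
    ggplot2::aes(x = .data$n, y = .data$total_distance)
  }
  ggplot2::ggplot(object, mapping) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "n (nearest sampled neighbor order)",
                  y = "total nth NN distance") +
    ggplot2::theme_minimal()
}

#' Plot benchmark AUROCs by method and subgroup
#'
#' Mean AUROC with across-dataset 95% confidence intervals, one panel per
#' evaluation group (overall and each true subgroup).
#'
#' @param object A `covr_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.covr_benchmark <- function(object, ...) {
  summ <- tidy(object)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$method, y = .data$mean_auroc,
                                     colour = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = "AUROC") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
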