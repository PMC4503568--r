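#' Plot a diversity-index distribution
#'
#' Bar chart of the percentage of markers per right-closed DI bin.
#'
#' @param object A `gbsdiv_di_histogram` from [di_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gbsdiv_di_histogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$bin_upper), y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "DI (bin upper edge, right-closed)",
                  y = "% of markers") +
    ggplot2::theme_minimal()
}

#' Plot a diversity summary
#'
#' Mean DI per level (linkage group, subgenome or panel), one panel per
#' group.
#'
#' @param object A `gbsdiv_diversity_summary` from [summarize_diversity()].
#' @param statistic `"mean_DI"` or `"mean_PIC"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gbsdiv_diversity_summary <- function(object, statistic = "mean_DI", ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$level_value, y = .data[[statistic]],
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = unique(object$level), y = statistic, fill = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot equal-size resampled diversities
#'
#' Group means with +/- 1 SD error bars over resampling replicates.
#'
#' @param object A `gbsdiv_resample_diversity` from
#'   [equal_size_resample_diversity()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gbsdiv_resample_diversity <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$group, y = .data$mean_DI)) +
    ggplot2::geom_col(fill = "darkseagreen") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_DI - .data$sd_DI,
                                        ymax = .data$mean_DI + .data$sd_DI),
                           width = 0.2) +
    ggplot2::labs(x = "group",
                  y = sprintf("mean DI (n = %d per group)", object$n[1])) +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
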