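#' Plot the substitution spectrum of a DNM set
#'
#' Bar chart of substitution-type counts, coloured by
#' transition/transversion class.
#'
#' @param candidates Candidate tibble with `substitution` and `ts_tv`.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(candidates) {
  spec <- substitution_spectrum(candidates)
  ggplot2::ggplot(spec, ggplot2::aes(
    x = stats::reorder(.data$substitution, -.data$n),
    y = .data$n, fill = .data$ts_tv)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "substitution", y = "DNM count", fill = NULL,
                  title = "De novo substitution spectrum") +
    ggplot2::theme_minimal()
}

#' Plot per-chromosome DNM counts with per-trio error bars
#'
#' @param chrom_summary Result of [per_chromosome_summary()] (or its
#'   `table` element).
#' @return A ggplot object.
#' @export
plot_chromosome_distribution <- function(chrom_summary) {
  tab <- if (is.list(chrom_summary) && !is.data.frame(chrom_summary)) {
    chrom_summary$table
  } else {
    chrom_summary
  }
  ggplot2::ggplot(tab, ggplot2::aes(
    x = factor(.data$chrom, levels = tab$chrom), y = .data$mean_per_trio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$mean_per_trio - .data$sem),
      ymax = .data$mean_per_trio + .data$sem), width = 0.3) +
    ggplot2::labs(x = NULL, y = "mean DNMs per trio",
                  title = "DNM distribution by chromosome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a rate estimate with its confidence interval
#'
#' @param object A `rate_estimate`.
#' @param ... Unused.
#' @return A ggplot object: point estimate with Wilson CI error bar.
#' @method autoplot rate_estimate
#' @export
autoplot.rate_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = "rate", y = .data$estimate)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high),
                           width = 0.1) +
    ggplot2::labs(x = NULL, y = "mutations per position per generation",
                  title = sprintf("De novo rate (%d events, %d trios)",
                                  object$n_mutations, object$n_trios)) +
    ggplot2::theme_minimal()
}
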