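# ggplot2 views of the package's result types.

#' Plot macro-averaged performance across MTTSI bins
#'
#' Precision/recall (and F) per identity bin with their confidence
#' intervals, optionally for several models side by side.
#'
#' @param macro Tibble from [macro_average()], or a named list of such
#'   tibbles (one per model).
#' @param metrics Metrics to show.
#' @return A ggplot object.
#' @export
plot_performance <- function(macro, metrics = c("precision", "recall")) {
  if (!is.data.frame(macro)) {
    macro <- dplyr::bind_rows(purrr::imap(macro, function(m, nm)
      dplyr::mutate(m, model = nm)))
  } else if (!"model" %in% names(macro)) {
    macro$model <- "model"
  }
  df <- dplyr::filter(macro, .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean,
                                   colour = .data$model,
                                   group = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "MTTSI bin (%)", y = "macro-averaged value",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot amino-acid propensities of rf-SDR positions
#'
#' @param propensity Tibble from [aa_propensity()].
#' @return A ggplot object.
#' @export
plot_propensity <- function(propensity) {
  ggplot2::ggplot(dplyr::filter(propensity, .data$defined),
                  ggplot2::aes(x = .data$residue, y = .data$propensity)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "amino acid", y = "rf-SDR propensity") +
    ggplot2::theme_bw()
}

#' Box plot of site-selection fractions by diversity class
#'
#' @param fractions Tibble with columns `class` and `fraction`.
#' @return A ggplot object.
#' @export
plot_fraction_by_class <- function(fractions) {
  fractions$class <- factor(fractions$class,
                            levels = c("low", "medium", "high"))
  ggplot2::ggplot(fractions, ggplot2::aes(x = .data$class,
                                          y = .data$fraction)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "functional diversity class",
                  y = "fraction of sites selected as rf-SDRs") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' Bar chart of a forest's attribute-importance ranking
#'
#' @param object An `efprf_importance` from [rank_importance()].
#' @param top_n Number of attributes shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.efprf_importance <- function(object, top_n = 20L, ...) {
  df <- head(dplyr::arrange(object, .data$rank), top_n)
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$name,
                                   fill = .data$highly_contributing)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "importance", y = NULL,
                  fill = "highly contributing") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
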