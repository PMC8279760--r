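#' Metagene coverage profile plot
#'
#' Per-bin central read fraction by genotype with SEM ribbons; the 3' bias
#' of degraded transcripts shows up as the mutant curve dipping below
#' control in the right-hand bins.
#'
#' @param metagene Output of [metagene_summary()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(metagene) {
  ggplot2::ggplot(metagene, ggplot2::aes(x = .data$bin, y = .data$mean_fraction,
                                         colour = .data$genotype,
                                         fill = .data$genotype)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_fraction - .data$sem,
                                      ymax = .data$mean_fraction + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "transcript position (percentile bin, 5' to 3')",
                  y = "median read fraction", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of translation-efficiency changes
#'
#' @param x A `te_fit` or its [tidy()] table.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_te_histogram <- function(x, bins = 60) {
  tbl <- if (inherits(x, "te_fit")) x$table else x
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$delta_te)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "red") +
    ggplot2::labs(x = expression(Delta * "TE (log2)"), y = "genes") +
    ggplot2::theme_minimal()
}

#' ECDF comparison plot for grouped values
#'
#' @param ecdf_tbl Tibble `group`, `value`, `cum_fraction` (e.g.
#'   `group_shift_test()$ecdf`).
#' @return A ggplot object.
#' @export
plot_ecdf <- function(ecdf_tbl) {
  ggplot2::ggplot(ecdf_tbl, ggplot2::aes(x = .data$value, y = .data$cum_fraction,
                                         colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "value", y = "cumulative fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential expression
#' @param x A `de_fit` or its [tidy()] table.
#' @return A ggplot object.
#' @export
plot_volcano <- function(x) {
  tbl <- if (inherits(x, "de_fit")) x$table else x
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$log2FC, y = -log10(.data$p),
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (mutant - control)",
                  y = "-log10 p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.te_fit <- function(object, ...) plot_te_histogram(object)

#' @export
autoplot.de_fit <- function(object, ...) plot_volcano(object)
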