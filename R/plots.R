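#' Plot a block map
#'
#' Shows each family's blocks as segments along the sequence coordinate,
#' starting at the canonical location and spanning the motif length.
#'
#' @param blocks Block tibble from [find_blocks()] or
#'   [riboswitch_blocks()].
#' @return A ggplot object.
#' @export
plot_block_map <- function(blocks) {
  df <- blocks |>
    mutate(end = .data$canonical_location + nchar(.data$motif) - 1L)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$family)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$canonical_location, xend = .data$end,
                   yend = .data$family),
      linewidth = 3, lineend = "butt", colour = "steelblue"
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = .data$canonical_location, label = .data$motif),
      vjust = -0.9, hjust = 0, size = 2.8
    ) +
    ggplot2::labs(x = "position (nt)", y = NULL,
                  title = "Family-specific sequential blocks") +
    ggplot2::theme_minimal()
}

#' Confusion heatmap for a confusion matrix
#'
#' @param object A `confusion_stats` object.
#' @param ... Unused.
#' @return A ggplot object (predicted vs true counts).
#' @method autoplot confusion_stats
#' @export
autoplot.confusion_stats <- function(object, ...) {
  df <- as.data.frame(as.table(object$counts))
  names(df) <- c("predicted", "true", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$predicted,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "true family", y = "predicted family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname autoplot.confusion_stats
#' @method autoplot riboblock_cv
#' @export
autoplot.riboblock_cv <- function(object, ...) {
  autoplot(object$confusion) +
    ggplot2::ggtitle(sprintf("%s, %d-fold CV, CCR %.2f%%",
                             toupper(object$classifier), object$config$v,
                             100 * object$ccr_mean))
}
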