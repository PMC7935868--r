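# ggplot2 views of depth profiles and annotation maps.

#' Plot a depth profile
#'
#' Windowed mean depth along one or all contigs of a depth object; a
#' hemizygous dip shows as a half-height step.
#'
#' @param depth A `circsig_depth` object.
#' @param contigs Contig ids to plot (default all).
#' @param window Averaging window, bases.
#' @return A ggplot object.
#' @export
plot_depth <- function(depth, contigs = NULL, window = 1000L) {
  tab <- depth_table(depth)
  if (!is.null(contigs)) tab <- tab[tab$contig %in% contigs, ]
  tab <- tab %>%
    dplyr::mutate(bin = (.data$pos %/% window) * window) %>%
    dplyr::group_by(.data$contig, .data$bin) %>%
    dplyr::summarise(depth = mean(.data$depth), .groups = "drop")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$bin / 1e3, y = .data$depth)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "position (kb)", y = "mean depth (x)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.circsig_depth <- function(object, ...) plot_depth(object, ...)

#' Plot an annotated contig map
#'
#' Contigs as horizontal bars with signature hits as coloured blocks, the
#' tabular analogue of an interactive genome-map view.
#'
#' @param object A `circsig_annotation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circsig_annotation <- function(object, ...) {
  cm <- object$contig_map %>% dplyr::distinct(.data$id, .data$length)
  cm$y <- seq_len(nrow(cm))
  hits <- object$hits %>%
    dplyr::left_join(cm, by = c(contig = "id"))
  g <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = cm,
                          ggplot2::aes(x = 0, xend = .data$length / 1e3,
                                       y = .data$y, yend = .data$y),
                          linewidth = 2, colour = "grey80")
  if (nrow(hits) > 0)
    g <- g + ggplot2::geom_rect(
      data = hits,
      ggplot2::aes(xmin = .data$start / 1e3, xmax = .data$end / 1e3,
                   ymin = .data$y - 0.3, ymax = .data$y + 0.3,
                   fill = .data$category))
  g + ggplot2::scale_y_continuous(breaks = cm$y, labels = cm$id) +
    ggplot2::labs(x = "position (kb)", y = NULL, fill = "category") +
    ggplot2::theme_minimal()
}
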