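#' Annotation heatmap of a residue track
#'
#' One coloured cell per position: pink for functional, metallic blue for
#' structural, yellow for adaptable, white for unlabeled, wrapped into rows
#' of `positions_per_row` positions.
#'
#' @param object An `fsa_track`.
#' @param positions_per_row Positions per heatmap row (default 60).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fsa_track <- function(object, positions_per_row = 60, ...) {
  if (nrow(object) == 0L) {
    abort("Cannot plot an empty annotation track.", class = "fsa_input_error")
  }
  df <- as_tibble(object) |>
    dplyr::mutate(
      row = (.data$position - 1) %/% positions_per_row,
      col = (.data$position - 1) %% positions_per_row
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row, fill = .data$label)) +
    ggplot2::geom_tile(colour = "grey70", linewidth = 0.2, width = 1, height = 0.8) +
    ggplot2::scale_fill_manual(values = fsa_palette(), drop = FALSE, name = NULL) +
    ggplot2::scale_x_continuous(
      breaks = seq(0, positions_per_row - 1, by = 10),
      labels = function(b) b + 1, expand = c(0, 0.5)
    ) +
    ggplot2::scale_y_continuous(
      breaks = -unique(df$row),
      labels = unique(df$row) * positions_per_row + 1
    ) +
    ggplot2::labs(x = "position (within row)", y = "row start") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank(),
                   legend.position = "bottom")
}

#' Render the annotation heatmap to an image file
#'
#' @param track An `fsa_track`.
#' @param out Output path; the extension selects the device (png, pdf, svg).
#' @param positions_per_row Positions per heatmap row.
#' @param width,height Device size in inches.
#' @return `out`, invisibly.
#' @export
render_heatmap <- function(track, out, positions_per_row = 60,
                           width = 10, height = NULL) {
  p <- autoplot.fsa_track(track, positions_per_row = positions_per_row)
  n_rows <- ceiling(nrow(track) / positions_per_row)
  height <- height %||% max(2, 0.5 * n_rows + 1.2)
  ggplot2::ggsave(out, p, width = width, height = height, dpi = 150)
  invisible(out)
}

#' Enrichment-map overview plot
#'
#' Tiles of -log10(p) per position and class; cells significant after the
#' information filter are outlined.
#'
#' @param object An `fsa_emap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fsa_emap <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$class)) +
    ggplot2::geom_tile(ggplot2::aes(fill = -log10(pmax(.data$p, 1e-16)))) +
    ggplot2::geom_tile(
      data = df[df$enriched, , drop = FALSE],
      fill = NA, colour = "black", linewidth = 0.4
    ) +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::labs(x = "position", y = NULL) +
    ggplot2::theme_minimal()
}

#' Filter-score profile plot
#'
#' Per-position information-scaled differential norm `s_i`, with discarded
#' (non-retained) positions greyed out.
#'
#' @param emap An `fsa_emap`.
#' @return A ggplot object.
#' @export
plot_filter_scores <- function(emap) {
  df <- dplyr::distinct(as_tibble(emap)[c("position", "filter_score", "retained")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$filter_score,
                                   colour = .data$retained)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0),
                          linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2C3E50", `FALSE` = "grey75"),
                                 name = "retained") +
    ggplot2::labs(x = "position", y = "information x differential norm") +
    ggplot2::theme_minimal()
}
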