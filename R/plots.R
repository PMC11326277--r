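#' Plot the spots of a stitched group
#'
#' Spots are drawn at their group full-resolution pixel coordinates, vertical
#' axis reversed to match image orientation. By default spots flagged
#' `exclude_overlapping` are hollow, mirroring how stitched data are usually
#' displayed (only the retained spot of each overlap is filled).
#'
#' @param object A `stitched_group`.
#' @param colour Spot annotation column mapped to colour
#'   (default `"capture_area"`).
#' @param show_excluded If `FALSE`, spots flagged `exclude_overlapping` are
#'   dropped from the plot entirely.
#' @param size Point size.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stitched_group
#' @export
autoplot.stitched_group <- function(object, colour = "capture_area",
                                    show_excluded = TRUE, size = 0.6, ...) {
  df <- object$spots
  if (!show_excluded) df <- df[!df$exclude_overlapping, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$pxl_col_in_fullres, y = .data$pxl_row_in_fullres,
    colour = .data[[colour]], shape = .data$exclude_overlapping
  )) +
    ggplot2::geom_point(size = size) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                name = "excluded\n(overlap)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = object$sample_id,
      x = "pxl_col_in_fullres (group frame)",
      y = "pxl_row_in_fullres (group frame)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot original versus artificial array coordinates
#'
#' Side-by-side view of a stitched group's spots positioned by pixel
#' coordinates and by their redefined artificial-array coordinates; useful to
#' check that the hexagonal snapping preserved the tissue arrangement.
#'
#' @param g A `stitched_group`.
#' @param size Point size.
#' @return A ggplot object (faceted).
#' @export
plot_array_coords <- function(g, size = 0.6) {
  stopifnot(inherits(g, "stitched_group"))
  pos <- array_position(g$lattice, g$spots$array_row, g$spots$array_col)
  df <- bind_rows(
    g$spots |>
      mutate(x = .data$pxl_col_in_fullres, y = .data$pxl_row_in_fullres,
             view = "transformed pixel coordinates"),
    g$spots |>
      mutate(x = pos$x, y = pos$y, view = "snapped to artificial array")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$capture_area)) +
    ggplot2::geom_point(size = size) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~view) +
    ggplot2::labs(x = "x (group fullres px)", y = "y (group fullres px)") +
    ggplot2::theme_minimal()
}
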