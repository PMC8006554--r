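#' Plot layout for a transplanted field trial
#'
#' Describes how rectangular per-line plot regions and the 3 x 3 grid of
#' plant centres inside each region map onto a top-down raster. The defaults
#' follow a transplanting design of plants 18 cm apart within rows and rows
#' 30 cm apart, imaged at 2 mm per pixel, giving 450 x 270 pixel plot
#' regions (90 px within-row spacing, 150 px row spacing). Rows run along
#' the image columns: the three row centres (150 px apart) span the 450 px
#' axis and the three within-row plant centres (90 px apart) span the 270 px
#' axis, so all nine centres lie strictly inside the region.
#'
#' @param plot_width_px,plot_height_px plot region size in pixels.
#' @param plant_spacing_px within-row plant spacing in pixels.
#' @param row_spacing_px spacing between rows in pixels.
#' @param resolution_mm_per_px ground resolution.
#' @param origin pixel coordinates (row, col), 0-based, of the field anchor:
#'   the top-left corner of the plot at grid position (0, 0).
#' @param grid named list mapping plot id to \code{c(row, col)} grid position
#'   of the plot's anchor; plot anchors tile the field at multiples of the
#'   plot size. Default: a single plot \code{"P1"} at (0, 0).
#' @return an object of class \code{plot_layout}.
#' @export
plot_layout <- function(plot_width_px = 450L, plot_height_px = 270L,
                        plant_spacing_px = 90L, row_spacing_px = 150L,
                        resolution_mm_per_px = 2,
                        origin = c(0L, 0L),
                        grid = list(P1 = c(0L, 0L))) {
  stopifnot(is_count(plot_width_px), is_count(plot_height_px),
            is_count(plant_spacing_px), is_count(row_spacing_px),
            resolution_mm_per_px > 0,
            length(origin) == 2L, all(origin >= 0),
            is.list(grid), length(grid) >= 1L, !is.null(names(grid)))
  layout <- structure(list(
    plot_width_px = as.integer(plot_width_px),
    plot_height_px = as.integer(plot_height_px),
    plant_spacing_px = as.integer(plant_spacing_px),
    row_spacing_px = as.integer(row_spacing_px),
    resolution_mm_per_px = resolution_mm_per_px,
    origin = as.integer(origin),
    grid = grid
  ), class = "plot_layout")
  pc <- plant_centres(layout)
  if (any(pc[, 1L] < 1L) || any(pc[, 1L] > plot_height_px) ||
      any(pc[, 2L] < 1L) || any(pc[, 2L] > plot_width_px))
    stop("plant centres do not lie strictly inside the plot region; ",
         "reduce spacings or enlarge the plot")
  layout
}

#' Half-scale variant of the default layout (4 mm per pixel)
#'
#' Convenience constructor used for desk-scale pipeline runs: the same field
#' geometry imaged at half the resolution (225 x 135 px regions, 45/75 px
#' spacings).
#' @param ... passed on to [plot_layout()] to override fields.
#' @export
plot_layout_half <- function(...) {
  args <- list(plot_width_px = 225L, plot_height_px = 135L,
               plant_spacing_px = 45L, row_spacing_px = 75L,
               resolution_mm_per_px = 4)
  do.call(plot_layout, utils::modifyList(args, list(...)))
}

#' Nine plant centres of a plot region
#'
#' Centres of the 3 x 3 plants, in region-local 1-based (row, col) pixel
#' coordinates, row-major in image order (top-left to bottom-right).
#'
#' @param layout a [plot_layout()].
#' @return integer matrix 9 x 2 with columns \code{row}, \code{col}.
#' @export
plant_centres <- function(layout) {
  stopifnot(inherits(layout, "plot_layout"))
  cr <- layout$plot_height_px %/% 2L   # centre, 0-based
  cc <- layout$plot_width_px %/% 2L
  dr <- c(-1L, 0L, 1L) * layout$plant_spacing_px   # within-row axis: rows
  dc <- c(-1L, 0L, 1L) * layout$row_spacing_px     # across rows: columns
  m <- cbind(row = rep(cr + dr, each = 3L) + 1L,
             col = rep(cc + dc, times = 3L) + 1L)
  m
}

#' Default per-plant tile side for a layout
#'
#' Largest odd tile side that keeps the nine tiles non-overlapping in the
#' tighter spacing direction: the greatest odd integer not exceeding
#' \code{min(plant_spacing_px, row_spacing_px) - 1}.
#' @param layout a [plot_layout()].
#' @export
default_tile_side <- function(layout) {
  stopifnot(inherits(layout, "plot_layout"))
  s <- min(layout$plant_spacing_px, layout$row_spacing_px) - 1L
  if (s %% 2L == 0L) s <- s - 1L
  as.integer(s)
}

#' @export
print.plot_layout <- function(x, ...) {
  cat(sprintf("plot_layout: %d x %d px regions, spacing %d/%d px, %g mm/px, %d plot(s)\n",
              x$plot_width_px, x$plot_height_px, x$plant_spacing_px,
              x$row_spacing_px, x$resolution_mm_per_px, length(x$grid)))
  invisible(x)
}
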