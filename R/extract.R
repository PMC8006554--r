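#' Extract one plot region from a field raster
#'
#' Crops the rectangle of a declared plot out of a larger raster, with no
#' resampling, and computes the nine plant centres from the layout
#' spacings. Rectangles follow the 0-based half-open convention
#' \code{[r0, r0 + h) x [c0, c0 + w)}, with the anchor of plot (row, col)
#' at \code{origin + (row * plot_height_px, col * plot_width_px)}.
#'
#' @param raster H x W x 3 numeric array (8-bit sRGB) or H x W matrix.
#' @param layout a [plot_layout()] whose \code{grid} names \code{plot_id}.
#' @param plot_id identifier of the plot to extract.
#' @return an object of class \code{plot_region}: list with \code{plot_id},
#'   \code{image} (the crop) and \code{plant_centres} (9 x 2, region-local
#'   1-based row/col).
#' @export
extract_plot_region <- function(raster, layout, plot_id) {
  stopifnot(inherits(layout, "plot_layout"))
  if (!plot_id %in% names(layout$grid))
    stop(sprintf("unknown plot_id '%s'", plot_id))
  nd <- length(dim(raster))
  if (!(nd %in% c(2L, 3L))) stop("raster must be a matrix or H x W x 3 array")
  H <- dim(raster)[1L]; W <- dim(raster)[2L]

  rc <- layout$grid[[plot_id]]
  r0 <- layout$origin[1L] + rc[1L] * layout$plot_height_px   # 0-based
  c0 <- layout$origin[2L] + rc[2L] * layout$plot_width_px
  r1 <- r0 + layout$plot_height_px
  c1 <- c0 + layout$plot_width_px
  if (r0 < 0 || c0 < 0 || r1 > H || c1 > W)
    stop(sprintf("plot '%s' rectangle [%d,%d)x[%d,%d) exceeds raster bounds %d x %d",
                 plot_id, r0, r1, c0, c1, H, W))

  image <- if (nd == 3L) raster[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]
           else raster[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  structure(list(plot_id = plot_id, image = image,
                 plant_centres = plant_centres(layout),
                 rect = c(r0 = r0, r1 = r1, c0 = c0, c1 = c1)),
            class = "plot_region")
}

#' Extract the nine per-plant square tiles
#'
#' Cuts a square tile of odd side centred on each of the nine plant centres,
#' in row-major plant order. Tiles must fit entirely inside the region.
#'
#' @param x a \code{plot_region}, or a matrix/array covering a full plot
#'   region (e.g. the \code{values} of a VF [segment_plants()] mask).
#' @param layout the [plot_layout()]; required when \code{x} is not a
#'   \code{plot_region} (centres are taken from it).
#' @param tile_side_px odd tile side in pixels; default
#'   [default_tile_side()] of the layout.
#' @return list of 9 tiles (matrices or arrays matching the input type).
#' @export
extract_plant_tiles <- function(x, layout = NULL, tile_side_px = NULL) {
  if (inherits(x, "plot_region")) {
    centres <- x$plant_centres
    values <- x$image
    if (is.null(tile_side_px)) {
      if (is.null(layout)) stop("tile_side_px or layout required")
      tile_side_px <- default_tile_side(layout)
    }
  } else {
    if (is.null(layout)) stop("layout required when x is a raw raster")
    centres <- plant_centres(layout)
    values <- x
    if (is.null(tile_side_px)) tile_side_px <- default_tile_side(layout)
  }
  if (tile_side_px %% 2L != 1L)
    stop("tile_side_px must be odd so tiles centre exactly on a pixel")
  h2 <- (tile_side_px - 1L) %/% 2L
  H <- dim(values)[1L]; W <- dim(values)[2L]
  nd <- length(dim(values))

  lapply(seq_len(9L), function(k) {
    r <- centres[k, 1L]; c <- centres[k, 2L]
    if (r - h2 < 1L || r + h2 > H || c - h2 < 1L || c + h2 > W)
      stop(sprintf("tile %d (side %d) overruns the region boundary; use a smaller tile_side_px",
                   k, tile_side_px))
    if (nd == 3L) values[(r - h2):(r + h2), (c - h2):(c + h2), , drop = FALSE]
    else values[(r - h2):(r + h2), (c - h2):(c + h2), drop = FALSE]
  })
}
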