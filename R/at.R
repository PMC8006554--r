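#' Merge nine per-plant binary tiles into a mean mask
#'
#' Pixel-wise arithmetic mean of the nine tiles; with binary inputs the
#' result takes values in \{0, 1/9, ..., 1\}.
#'
#' @param tiles list of exactly 9 square binary matrices of identical odd
#'   side (as returned by [extract_plant_tiles()] on a mask).
#' @return numeric matrix in [0, 1] (the mean mask).
#' @export
merge_tiles <- function(tiles) {
  if (!is.list(tiles) || length(tiles) != 9L)
    stop("exactly nine tiles are required")
  d <- dim(tiles[[1L]])
  if (is.null(d) || length(d) != 2L || d[1L] != d[2L] || d[1L] %% 2L != 1L)
    stop("tiles must be square matrices of odd side")
  for (t in tiles) {
    if (!identical(dim(t), d)) stop("tiles have mismatched dimensions")
    if (any(t < 0 | t > 1)) stop("tile values must lie in [0, 1]")
  }
  Reduce(`+`, lapply(tiles, function(t) t / 9))
}

#' Archery-target region map: five concentric weighted regions
#'
#' Partitions an odd-sided square into five concentric regions labelled
#' \code{a} (outermost) to \code{e} (innermost), weighted 1 to 5 from the
#' outside to the centre. Region boundaries sit at fractions
#' \{0.2, 0.4, 0.6, 0.8, 1.0\} of the half-side. In \code{"square-annuli"}
#' mode the regions are nested square frames (max-norm distance from the
#' centre pixel) and partition the raster exactly; in
#' \code{"circular-annuli"} mode they are circular rings (Euclidean
#' distance) and corner pixels outside the largest circle belong to no
#' region (and are excluded from all means). Boundary pixels belong to the
#' inner region; the centre pixel is in region \code{e}.
#'
#' @param side odd side length in pixels. Every region must be non-empty,
#'   which in square-annuli mode requires \code{side >= 9}.
#' @param shape_mode \code{"square-annuli"} (default) or
#'   \code{"circular-annuli"}.
#' @return an object of class \code{at_regions}: list with \code{labels}
#'   (character matrix \code{"a"}..\code{"e"}, \code{NA} outside the
#'   largest circle), \code{weights} (named a = 1 .. e = 5), \code{areas}
#'   (pixel counts per region), \code{side}, \code{shape_mode}.
#' @export
define_regions <- function(side, shape_mode = c("square-annuli", "circular-annuli")) {
  shape_mode <- match.arg(shape_mode)
  if (!is_count(side) || side %% 2L != 1L || side < 5L)
    stop("side must be an odd integer >= 5")
  c0 <- (side - 1) / 2                       # centre pixel, 0-based
  off <- seq_len(side) - 1 - c0              # signed offsets from centre
  if (shape_mode == "square-annuli") {
    d <- outer(abs(off), abs(off), pmax)     # max-norm distance
  } else {
    d <- sqrt(outer(off^2, off^2, `+`))      # Euclidean distance
  }
  bounds <- (side / 2) * c(0.2, 0.4, 0.6, 0.8, 1.0)
  # region index: 1 = innermost (d <= 0.2*half-side), boundary -> inner (<=)
  idx <- matrix(findInterval(d, bounds, left.open = TRUE) + 1L, side, side)
  lab <- matrix(c("e", "d", "c", "b", "a", NA)[pmin(idx, 6L)], side, side)
  areas <- vapply(c("a", "b", "c", "d", "e"),
                  function(l) sum(lab == l, na.rm = TRUE), integer(1L))
  if (any(areas == 0L))
    stop(sprintf("side %d is too small for five non-empty %s regions", side, shape_mode))
  structure(list(labels = lab,
                 weights = c(a = 1, b = 2, c = 3, d = 4, e = 5),
                 areas = areas, side = as.integer(side),
                 shape_mode = shape_mode),
            class = "at_regions")
}

#' Custom archery-target region map from a label matrix
#'
#' Escape hatch for non-default geometries (e.g. equal-area regions):
#' builds an \code{at_regions} object from an explicit label matrix with
#' values \code{"a"}..\code{"e"} (or \code{NA} for excluded pixels), with
#' the fixed weights 1..5 outside to centre.
#' @param labels square character matrix.
#' @export
region_map <- function(labels) {
  if (!is.matrix(labels) || nrow(labels) != ncol(labels))
    stop("labels must be a square matrix")
  ok <- labels %in% c("a", "b", "c", "d", "e") | is.na(labels)
  if (!all(ok)) stop("labels must be 'a'..'e' or NA")
  areas <- vapply(c("a", "b", "c", "d", "e"),
                  function(l) sum(labels == l, na.rm = TRUE), integer(1L))
  if (any(areas == 0L)) stop("every region a..e must be non-empty")
  structure(list(labels = labels,
                 weights = c(a = 1, b = 2, c = 3, d = 4, e = 5),
                 areas = areas, side = nrow(labels),
                 shape_mode = "custom"),
            class = "at_regions")
}

#' Archery-target (AT) architecture score
#'
#' AT = sum over regions of (weight_i x region mean) / overall mean, where
#' region means are arithmetic means of the mask over each region's pixels
#' and the overall mean is taken over all partition pixels. A mask that is
#' uniform over the partition scores exactly 15 (= 1+2+3+4+5); mass
#' concentrated towards the centre raises the score, so more upright,
#' compact plants score higher and spreading plants lower. The score is
#' invariant to scaling the mask by any positive constant.
#'
#' @param mask mean mask matrix (from [merge_tiles()]), side matching
#'   \code{regions}.
#' @param regions an \code{at_regions} from [define_regions()] or
#'   [region_map()].
#' @return an object of class \code{at_score}: list with \code{at},
#'   \code{region_means} (named a..e), \code{overall_mean},
#'   \code{shape_mode}.
#' @export
compute_at <- function(mask, regions) {
  stopifnot(inherits(regions, "at_regions"))
  if (!is.matrix(mask) || !all(dim(mask) == regions$side))
    stop("mask dimensions must match the region map side")
  if (any(!is.finite(mask)) || any(mask < 0))
    stop("mask values must be finite and non-negative")
  lab <- regions$labels
  use <- !is.na(lab)
  overall <- mean(mask[use])
  if (overall == 0)
    stop("mask has no plant signal within the regions: AT undefined (division by the overall mean)")
  means <- vapply(c("a", "b", "c", "d", "e"),
                  function(l) mean(mask[use][lab[use] == l]), numeric(1L))
  at <- sum(regions$weights * means) / overall
  structure(list(at = at, region_means = means, overall_mean = overall,
                 shape_mode = regions$shape_mode),
            class = "at_score")
}

#' Measure the AT score of a segmented plot region
#'
#' Convenience wrapper: cut the nine plant tiles out of a VF mask, merge
#' them, and score against the concentric-region map.
#'
#' @param mask a \code{binary_mask} from [segment_plants()] (or 0/1 matrix)
#'   covering a full plot region.
#' @param layout the [plot_layout()] locating the nine plants.
#' @param tile_side_px odd tile side; default [default_tile_side()].
#' @param shape_mode passed to [define_regions()].
#' @return an \code{at_score}.
#' @export
measure_at <- function(mask, layout, tile_side_px = NULL,
                       shape_mode = "square-annuli") {
  values <- if (inherits(mask, "binary_mask")) mask$values else mask
  if (is.null(tile_side_px)) tile_side_px <- default_tile_side(layout)
  tiles <- extract_plant_tiles(values, layout, tile_side_px)
  compute_at(merge_tiles(tiles), define_regions(tile_side_px, shape_mode))
}

#' @export
print.at_score <- function(x, ...) {
  cat(sprintf("AT score %.3f (%s; region means %s; overall %.4f)\n",
              x$at, x$shape_mode,
              paste(sprintf("%s=%.3f", names(x$region_means), x$region_means),
                    collapse = " "),
              x$overall_mean))
  invisible(x)
}
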