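#' Segment plant pixels from an a* image
#'
#' The a* channel is rescaled per image to the 0..255 range (min to 0, max
#' to 255), rounded to integer bins, and thresholded with Otsu's method on
#' the resulting 256-bin histogram. The plant class is the low-a* side
#' (green); the threshold bin itself belongs to the plant class. Set
#' \code{polarity = "high"} to invert (useful for sanity checks), and
#' \code{rescale = FALSE} to quantize a fixed a* range of [-128, 128)
#' instead of the per-image range.
#'
#' @param astar numeric matrix of a* values (see [rgb_to_astar()]).
#' @param polarity which side of the threshold is called plant.
#' @param rescale rescale a* per image before quantization (default), or
#'   clamp to the fixed range [-128, 128).
#' @return an object of class \code{binary_mask}: list with \code{values}
#'   (integer 0/1 matrix, 1 = plant), \code{threshold_astar} (upper edge of
#'   the threshold bin, in original a* units), \code{threshold_bin},
#'   \code{n_plant}, \code{n_total}.
#' @export
segment_plants <- function(astar, polarity = c("low", "high"), rescale = TRUE) {
  polarity <- match.arg(polarity)
  if (!is.matrix(astar) || !is.numeric(astar) || length(astar) == 0L)
    stop("astar must be a non-empty numeric matrix")
  if (any(!is.finite(astar))) stop("astar contains non-finite values")

  if (rescale) {
    rng <- range(astar)
    if (diff(rng) == 0)
      stop("constant a* image: Otsu threshold undefined")
    bins <- as.integer(round((astar - rng[1L]) / diff(rng) * 255))
    # upper edge of bin t (values rounding to t), back in original a* units
    bin_to_astar <- function(t) rng[1L] + (t + 0.5) / 255 * diff(rng)
  } else {
    bins <- as.integer(pmax(0, pmin(255, floor(astar) + 128)))
    bin_to_astar <- function(t) (t + 1) - 128
  }
  counts <- tabulate(bins + 1L, nbins = 256L)
  t <- otsu_threshold(counts)

  plant <- bins <= t
  if (polarity == "high") plant <- !plant
  values <- matrix(as.integer(plant), nrow(astar), ncol(astar))
  structure(list(values = values,
                 threshold_astar = bin_to_astar(t),
                 threshold_bin = t,
                 polarity = polarity,
                 n_plant = sum(values),
                 n_total = length(values)),
            class = "binary_mask")
}

#' Vegetation fraction of a binary plant mask
#'
#' VF is the percentage of plant pixels among all pixels of the plot
#' region: \code{100 * n_plant / n_total}.
#'
#' @param mask a \code{binary_mask} from [segment_plants()], or a 0/1 matrix.
#' @return VF in percent, in [0, 100].
#' @export
compute_vf <- function(mask) {
  values <- if (inherits(mask, "binary_mask")) mask$values else mask
  if (!is.matrix(values) || length(values) == 0L)
    stop("empty mask: VF undefined")
  if (!all(values %in% c(0L, 1L)))
    stop("mask values must be 0/1")
  100 * sum(values) / length(values)
}

#' Measure VF of an RGB plot region
#'
#' Convenience wrapper: a* conversion, Otsu segmentation, VF.
#'
#' @param image H x W x 3 8-bit sRGB array.
#' @param ... passed to [segment_plants()].
#' @return list with \code{vf} (percent), \code{mask} (the
#'   \code{binary_mask}), \code{threshold_astar}.
#' @export
measure_vf <- function(image, ...) {
  mask <- segment_plants(rgb_to_astar(image), ...)
  list(vf = compute_vf(mask), mask = mask,
       threshold_astar = mask$threshold_astar)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d px, %d plant (%.1f%%), a* threshold %.2f\n",
              nrow(x$values), ncol(x$values), x$n_plant,
              100 * x$n_plant / x$n_total, x$threshold_astar))
  invisible(x)
}
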