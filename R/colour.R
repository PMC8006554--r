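#' Convert an 8-bit sRGB image to the CIELAB a* channel
#'
#' Green vegetation sits on the negative side of the a* (red-green opponent)
#' axis while soil and water sit near zero or on the positive side, which is
#' what makes a* the channel of choice for canopy segmentation. The
#' conversion follows the standard sRGB pipeline: inverse companding with
#' the piecewise curve (linear segment below 0.04045, exponent 2.4 above),
#' the IEC sRGB RGB-to-XYZ matrix, and CIELAB under the D65 white point
#' (2 degree observer). The white point is taken as the matrix row sums so
#' that achromatic pixels (R = G = B) map to a* = 0 exactly.
#'
#' @param image numeric array H x W x 3 with 8-bit sRGB values in 0..255,
#'   or an N x 3 matrix of pixels.
#' @return for an array input, an H x W matrix of a* values; for a matrix
#'   input, a numeric vector of length N.
#' @examples
#' rgb_to_astar(matrix(c(128, 128, 128), 1))       # 0: achromatic
#' rgb_to_astar(matrix(c(0, 255, 0), 1))           # about -86.18: pure green
#' @export
rgb_to_astar <- function(image) {
  if (is.matrix(image) && ncol(image) == 3L) {
    px <- image
    out_dim <- NULL
  } else if (is.array(image) && length(dim(image)) == 3L && dim(image)[3L] == 3L) {
    d <- dim(image)
    px <- cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
                as.vector(image[, , 3L]))
    out_dim <- d[1:2]
  } else {
    stop("input must be an H x W x 3 array or an N x 3 matrix of 8-bit sRGB values")
  }
  if (any(!is.finite(px)) || any(px < 0) || any(px > 255))
    stop("sRGB values must be finite and within 0..255")

  v <- px / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  # sRGB -> XYZ at full precision, derived from the IEC 61966-2-1 primary
  # chromaticities R(0.64, 0.33), G(0.30, 0.60), B(0.15, 0.06) and the
  # D65 white (x, y) = (0.3127, 0.3290)
  M <- matrix(c(0.4123907992659594, 0.3575843393838780, 0.1804807884018343,
                0.2126390058715103, 0.7151686787677559, 0.0721923153607337,
                0.0193308187155918, 0.1191947797946260, 0.9505321522496607),
              nrow = 3L, byrow = TRUE)
  XYZ <- lin %*% t(M)
  white <- rowSums(M)   # D65, consistent with the matrix: grey -> a* = 0 exactly

  delta <- 6 / 29
  flab <- function(t) ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
  astar <- 500 * (flab(XYZ[, 1L] / white[1L]) - flab(XYZ[, 2L] / white[2L]))

  if (is.null(out_dim)) astar else matrix(astar, out_dim[1L], out_dim[2L])
}
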