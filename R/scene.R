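#' Simulate a top-down canopy scene with ground truth
#'
#' Renders one plot region - a 3 x 3 grid of rice plants seen from above -
#' as an 8-bit RGB raster plus the exact plant/background mask it was drawn
#' from. Each plant is a rosette of 8-15 elliptical leaves radiating from
#' its centre at uniformly random angles. The \code{spread} parameter
#' controls growth habit: leaf length is proportional to
#' \code{0.5 + spread} and leaves are offset outwards from the centre in
#' proportion to \code{spread}, so low values give a compact, centrally
#' dense plant (upright habit) and high values a spreading one. Leaf sizes
#' are then scaled isotropically by bisection until the plant-pixel
#' fraction of the whole region hits \code{coverage_target} (within
#' 0.03, typically much closer).
#'
#' Plant pixels are coloured around RGB (40, 120, 35) and background pixels
#' around soil-like (110, 95, 80), with a shared-luminance jitter of +/-15
#' and a per-channel chroma jitter of +/-4 per pixel: the classes sit on
#' opposite sides of a* = 0 (background stays at a* > -5) without making
#' segmentation trivial. All randomness comes from a private stream seeded
#' with \code{seed}; identical arguments give bit-identical scenes.
#'
#' @param layout a [plot_layout()]; leaf dimensions scale with
#'   \code{plant_spacing_px}, so scenes are resolution-independent.
#' @param coverage_target target plant-pixel fraction, in [0, 0.8].
#' @param spread spreading-habit parameter in [0, 1].
#' @param seed integer seed.
#' @param size_jitter per-plant size multiplier drawn from
#'   \code{U(1 - size_jitter, 1 + size_jitter)} (within-line variability
#'   among the nine plants; default 0.1).
#' @return an object of class \code{canopy_scene}: list with \code{image}
#'   (H x W x 3 integer array, 0..255), \code{truth_mask} (H x W integer
#'   0/1 matrix), \code{truth_vf} (fraction in [0, 1]),
#'   \code{coverage_target}, \code{spread}, \code{seed}.
#' @export
gen_canopy_scene <- function(layout, coverage_target, spread, seed,
                             size_jitter = 0.1) {
  stopifnot(inherits(layout, "plot_layout"),
            is.numeric(coverage_target), length(coverage_target) == 1L,
            is.numeric(spread), length(spread) == 1L,
            size_jitter >= 0, size_jitter < 1)
  if (coverage_target < 0 || coverage_target > 0.8)
    stop("coverage_target must lie in [0, 0.8]")
  if (spread < 0 || spread > 1) stop("spread must lie in [0, 1]")

  h <- layout$plot_height_px
  w <- layout$plot_width_px
  centres <- plant_centres(layout)
  base_len <- 0.61 * layout$plant_spacing_px
  base_w <- 0.115 * layout$plant_spacing_px

  local_seed(seed, {
    # one draw of all stochastic leaf geometry; calibration is deterministic
    plants <- lapply(seq_len(9L), function(k) {
      nl <- sample(8:15, 1L)
      list(nl = nl,
           theta = stats::runif(nl, 0, 2 * pi),
           u = stats::runif(nl, 0.55, 1),
           wj = stats::runif(nl, 0.85, 1.15),
           pj = stats::runif(1L, 1 - size_jitter, 1 + size_jitter))
    })

    if (coverage_target == 0) {
      mask <- matrix(FALSE, h, w)
    } else {
      frac <- function(m, step) {
        mean(render_leaf_mask(h, w, centres, plants, spread,
                              base_len, base_w, m, step))
      }
      # coarse calibration on a 2x-decimated lattice, monotone in m
      lo <- 0; hi <- 0.35
      f_hi <- frac(hi, 2L)
      while (f_hi < coverage_target && hi < 10) {
        lo <- hi; hi <- hi * 1.6
        f_hi <- frac(hi, 2L)
      }
      if (f_hi < coverage_target - 0.01)
        stop(sprintf("coverage_target %.2f infeasible for this layout (max reachable ~%.2f)",
                     coverage_target, f_hi))
      best_m <- hi; best_err <- abs(f_hi - coverage_target)
      for (it in seq_len(28L)) {
        mid <- (lo + hi) / 2
        fm <- frac(mid, 2L)
        err <- abs(fm - coverage_target)
        if (err < best_err) { best_m <- mid; best_err <- err }
        if (err <= 0.003) break
        if (fm < coverage_target) lo <- mid else hi <- mid
      }
      mask <- render_leaf_mask(h, w, centres, plants, spread,
                               base_len, base_w, best_m, 1L)
      # polish at full resolution if decimation error pushed us off target
      if (abs(mean(mask) - coverage_target) > 0.01) {
        lo2 <- best_m * 0.85; hi2 <- best_m * 1.18
        for (it in seq_len(8L)) {
          mid <- (lo2 + hi2) / 2
          mm <- render_leaf_mask(h, w, centres, plants, spread,
                                 base_len, base_w, mid, 1L)
          err <- abs(mean(mm) - coverage_target)
          if (err < abs(mean(mask) - coverage_target)) { mask <- mm; best_m <- mid }
          if (err <= 0.003) break
          if (mean(mm) < coverage_target) lo2 <- mid else hi2 <- mid
        }
      }
    }

    truth_vf <- mean(mask)
    if (abs(truth_vf - coverage_target) > 0.03)
      stop(sprintf("calibration failed: realized cover %.3f vs target %.3f",
                   truth_vf, coverage_target))

    # colours: per-pixel luminance jitter (+/-15, shared across channels)
    # plus a small per-channel chroma jitter (+/-4). Keeping most of the
    # variation achromatic bounds the background a* near zero (soil stays
    # on the non-green side) while still spreading both class histograms.
    img <- array(0L, dim = c(h, w, 3L))
    plant_base <- c(40L, 120L, 35L)
    bg_base <- c(110L, 95L, 80L)
    n1 <- sum(mask); n0 <- h * w - n1
    lum0 <- sample(-15:15, n0, replace = TRUE)
    lum1 <- if (n1 > 0) sample(-15:15, n1, replace = TRUE) else integer(0)
    for (ch in 1:3) {
      mat <- matrix(0L, h, w)
      mat[!mask] <- bg_base[ch] + lum0 + sample(-4:4, n0, replace = TRUE)
      if (n1 > 0)
        mat[mask] <- plant_base[ch] + lum1 + sample(-4:4, n1, replace = TRUE)
      img[, , ch] <- pmax(0L, pmin(255L, mat))
    }

    structure(list(image = img,
                   truth_mask = matrix(as.integer(mask), h, w),
                   truth_vf = truth_vf,
                   coverage_target = coverage_target,
                   spread = spread, seed = as.integer(seed)),
              class = "canopy_scene")
  })
}

# Rasterize the leaf ellipses of all nine plants onto the pixel lattice
# (optionally decimated by `step` for cheap area estimates during
# calibration). `m` is the isotropic size multiplier under calibration.
render_leaf_mask <- function(h, w, centres, plants, spread,
                             base_len, base_w, m, step = 1L) {
  ys <- seq(1L, h, by = step)
  xs <- seq(1L, w, by = step)
  mask <- matrix(FALSE, length(ys), length(xs))
  len_fac <- base_len * (0.5 + spread) * m
  for (k in seq_len(9L)) {
    p <- plants[[k]]
    cy <- centres[k, 1L]; cx <- centres[k, 2L]
    for (l in seq_len(p$nl)) {
      a <- len_fac * p$u[l] * p$pj / 2            # semi-major (along leaf)
      b <- base_w * p$wj[l] * p$pj * m / 2        # semi-minor
      if (a < 0.35 || b < 0.2) next
      off <- 0.3 * spread * 2 * a                 # push leaves outwards when spreading
      ct <- cos(p$theta[l]); st <- sin(p$theta[l])
      ecx <- cx + (off + a) * ct
      ecy <- cy + (off + a) * st
      ext <- a + 1
      i0 <- max(1L, floor((ecy - ext - 1) / step) + 1L)
      i1 <- min(length(ys), ceiling((ecy + ext - 1) / step) + 1L)
      j0 <- max(1L, floor((ecx - ext - 1) / step) + 1L)
      j1 <- min(length(xs), ceiling((ecx + ext - 1) / step) + 1L)
      if (i0 > i1 || j0 > j1) next
      dy <- ys[i0:i1] - ecy
      dx <- xs[j0:j1] - ecx
      xr <- outer(dy * st, dx * ct, `+`)          # along-leaf coordinate
      yr <- outer(dy * ct, -dx * st, `+`)         # across-leaf coordinate
      inside <- (xr / a)^2 + (yr / b)^2 <= 1
      if (any(inside)) {
        sub <- mask[i0:i1, j0:j1, drop = FALSE]
        mask[i0:i1, j0:j1] <- sub | inside
      }
    }
  }
  mask
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("canopy_scene: %d x %d px, truth VF %.3f (target %.2f), spread %.2f, seed %d\n",
              nrow(x$truth_mask), ncol(x$truth_mask), x$truth_vf,
              x$coverage_target, x$spread, x$seed))
  invisible(x)
}
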