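# Independent reference implementations ("oracles") used to validate the
# package's own routines. These deliberately take different computational
# routes from the code under test.

# Brute-force Otsu: direct between-class variance at every split, plus the
# companion within-class variance, with the same midpoint tie rule.
oracle_otsu <- function(counts) {
  counts <- as.numeric(counts)
  N <- sum(counts)
  levels <- 0:255
  bcv <- wcv <- rep(NA_real_, 255)
  for (t in 0:254) {
    lo <- 1:(t + 1); hi <- (t + 2):256
    n0 <- sum(counts[lo]); n1 <- N - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[lo] * levels[lo]) / n0
    mu1 <- sum(counts[hi] * levels[hi]) / n1
    w0 <- n0 / N; w1 <- n1 / N
    bcv[t + 1] <- w0 * w1 * (mu0 - mu1)^2
    v0 <- sum(counts[lo] * (levels[lo] - mu0)^2) / n0
    v1 <- sum(counts[hi] * (levels[hi] - mu1)^2) / n1
    wcv[t + 1] <- w0 * v0 + w1 * v1
  }
  opt <- which(bcv == max(bcv, na.rm = TRUE)) - 1L
  opt_w <- which(wcv == min(wcv, na.rm = TRUE)) - 1L
  list(threshold = as.integer((min(opt) + max(opt)) %/% 2L),
       optimal_set = opt, optimal_set_within = opt_w)
}

# Reference sRGB -> CIELAB a*: the RGB->XYZ matrix is derived from the sRGB
# primary chromaticities and the D65 white rather than hard-coded.
oracle_astar <- function(px) {
  P <- sapply(list(c(0.64, 0.33), c(0.30, 0.60), c(0.15, 0.06)),
              function(xy) c(xy[1] / xy[2], 1, (1 - xy[1] - xy[2]) / xy[2]))
  w <- c(0.3127, 0.3290)
  white <- c(w[1] / w[2], 1, (1 - w[1] - w[2]) / w[2])
  M <- P %*% diag(as.vector(solve(P, white)))
  v <- px / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  XYZ <- lin %*% t(M)
  wn <- rowSums(M)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  500 * (f(XYZ[, 1] / wn[1]) - f(XYZ[, 2] / wn[2]))
}

# Kruskal-Wallis via the variance-ratio identity on ranks,
# H = (N - 1) * SS_between / SS_total, with mid-ranks computed by counting
# comparisons rather than rank().
oracle_kw <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
  g <- rep.int(seq_along(groups), lengths(groups))
  rbar <- mean(r)
  ss_between <- sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - rbar)^2))
  ss_total <- sum((r - rbar)^2)
  if (ss_total == 0) return(NA_real_)
  (N - 1) * ss_between / ss_total
}

# Exhaustive peak caller: scan every index for the strict-local-maximum /
# leftmost-plateau condition, then greedy selection by height.
oracle_find_peaks <- function(x, min_distance, n_top) {
  x <- as.numeric(x)
  x[!is.finite(x)] <- -Inf
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L   # plateau [i, j]
    if (j <= n - 1L && is.finite(x[i]) &&
        x[i] > x[i - 1L] && x[i] > x[j + 1L])
      cand <- c(cand, i)
    i <- j + 1L
  }
  if (length(cand) == 0L)
    return(data.frame(index = integer(0), height = numeric(0), rank = integer(0)))
  h <- x[cand]
  ord <- order(-h, cand)
  sel <- integer(0)
  for (k in ord) {
    if (length(sel) >= n_top) break
    if (all(abs(cand[k] - cand[sel]) >= min_distance)) sel <- c(sel, k)
  }
  data.frame(index = cand[sel], height = h[sel], rank = seq_along(sel))
}

# small fast layout for scene-based tests (75 x 45 px plots)
layout_small <- function() {
  plot_layout(plot_width_px = 75L, plot_height_px = 45L,
              plant_spacing_px = 15L, row_spacing_px = 25L,
              resolution_mm_per_px = 12)
}

# random 256-bin histogram with at least two occupied bins
random_histogram <- function() {
  repeat {
    k <- sample(2:40, 1)
    bins <- sample(0:255, k)
    counts <- integer(256)
    counts[bins + 1] <- sample(1:200, k, replace = TRUE)
    if (sum(counts > 0) >= 2) return(counts)
  }
}

# equal-area five-region geometry: vertical stripes of 3 columns on a
# 15 x 15 raster (45 px per region); regions need not be concentric for
# the AT formula itself.
equal_area_regions <- function() {
  lab <- matrix(rep(c("a", "b", "c", "d", "e"), each = 45), 15, 15)
  region_map(lab)
}
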