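#' Otsu threshold of a 256-bin histogram
#'
#' Returns the bin index t (0-based, in 0..254) that splits the histogram
#' into a low class \code{[0..t]} and a high class \code{[t+1..255]} while
#' maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}. The search is exhaustive over
#' all 255 candidate splits. The between-class variance is evaluated in the
#' exact-integer form \eqn{(N S_1(t) - S_0(t) T)^2 / (S_0(t)(N - S_0(t)))}
#' (a positive multiple, \eqn{N^2}, of the usual expression), where
#' \eqn{S_0} and \eqn{S_1} are cumulative counts and count-weighted level
#' sums: with integer counts this is reproducible to the last bit regardless
#' of summation order.
#'
#' Ties: when several splits attain the maximum (e.g. a perfectly symmetric
#' two-spike histogram), the midpoint of the optimal range is returned,
#' rounded down.
#'
#' @param counts integer vector of length 256: pixel counts per level 0..255.
#' @return integer threshold bin in 0..254.
#' @export
otsu_threshold <- function(counts) {
  if (length(counts) != 256L)
    stop("expected a 256-bin histogram")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("histogram counts must be non-negative and finite")
  N <- sum(counts)
  if (N <= 0) stop("histogram is empty")
  if (sum(counts > 0) < 2L)
    stop("histogram has a single occupied bin: image is constant, threshold undefined")

  counts <- as.numeric(counts)    # doubles are exact here (counts << 2^53)
  levels <- 0:255
  S0 <- cumsum(counts)            # cumulative count up to level t
  S1 <- cumsum(counts * levels)   # cumulative level sum up to t
  T1 <- S1[256L]

  t_cand <- 0:254
  n0 <- S0[t_cand + 1L]
  valid <- n0 > 0 & n0 < N
  num <- (N * S1[t_cand + 1L] - n0 * T1)^2
  bcv <- rep(-Inf, 255L)
  bcv[valid] <- num[valid] / (n0[valid] * (N - n0[valid]))

  opt <- which(bcv == max(bcv)) - 1L   # 0-based optimal thresholds
  as.integer((min(opt) + max(opt)) %/% 2L)
}
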