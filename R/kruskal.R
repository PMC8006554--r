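#' Kruskal-Wallis rank sum test
#'
#' Nonparametric one-way analysis of variance on ranks, the per-SNP test of
#' the haplotype-based GWAS. Observations are ranked jointly with mid-ranks
#' for ties; the statistic is
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar r_i - (N+1)/2)^2}
#' divided by the tie correction \eqn{1 - \sum_g (t_g^3 - t_g)/(N^3 - N)}
#' over tie groups of sizes \eqn{t_g}. The p-value is the upper chi-squared
#' tail with \eqn{k - 1} degrees of freedom.
#'
#' When all N values are identical the tie correction is zero and the test
#' is undefined: the result is flagged degenerate with \code{H} and
#' \code{p} set to \code{NA}.
#'
#' @param groups list of k >= 2 numeric vectors, each non-empty, total
#'   N >= 3.
#' @return list with \code{H}, \code{df} (= k - 1), \code{p}, \code{n}
#'   (total N) and \code{degenerate}.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))  # H = 7.2
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least two groups are required")
  n_i <- lengths(groups)
  if (any(n_i < 1L)) stop("every group must contain at least one value")
  x <- unlist(groups, use.names = FALSE)
  if (!is.numeric(x) || any(!is.finite(x))) stop("values must be finite numerics")
  N <- length(x)
  if (N < 3L) stop("total sample size must be at least 3")
  g <- rep.int(seq_along(groups), n_i)
  out <- kw_core(x, g, length(groups))
  c(out, list(n = N))
}

# Core statistic on a value vector + integer group labels (1..k).
# Shared by kruskal_wallis() and the GWAS scan fast path; `r` and
# `tie_term` can be supplied pre-computed when the same phenotype vector is
# tested against many SNP groupings.
kw_core <- function(x, g, k, r = NULL, tie_term = NULL) {
  N <- length(x)
  if (is.null(r)) r <- rank(x)           # mid-ranks for ties
  if (is.null(tie_term)) {
    t_g <- tabulate(match(x, x))
    t_g <- t_g[t_g > 0L]
    tie_term <- sum(t_g^3 - t_g)
  }
  C <- 1 - tie_term / (N^3 - N)
  df <- k - 1L
  if (C <= 0)
    return(list(H = NA_real_, df = df, p = NA_real_, degenerate = TRUE))
  Ri <- rowsum(r, g, reorder = TRUE)[, 1L]
  ni <- tabulate(g, nbins = k)
  H0 <- 12 / (N * (N + 1)) * sum(ni * (Ri / ni - (N + 1) / 2)^2)
  H <- H0 / C
  list(H = H, df = df, p = stats::pchisq(H, df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Compares two groups of lines (e.g. lines partitioned by founder-allele
#' class at a candidate gene) with the classical pooled-variance t
#' statistic and a two-sided p-value. With zero pooled variance the test
#' returns p = 1 when the means agree and is flagged degenerate otherwise.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return list with \code{t}, \code{df}, \code{p}, \code{tier}
#'   (significance annotation: ** p<0.01, * p<0.05, + p<0.1) and
#'   \code{degenerate}.
#' @export
group_compare <- function(values_a, values_b) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least two values")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (dm == 0)
      return(list(t = 0, df = df, p = 1, tier = "", degenerate = FALSE))
    return(list(t = NA_real_, df = df, p = NA_real_, tier = NA_character_,
                degenerate = TRUE))
  }
  t <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, tier = signif_tier(p), degenerate = FALSE)
}
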