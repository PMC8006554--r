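#' Simulation configuration for the synthetic MAGIC population
#'
#' Bundles the population and genome parameters of the synthetic-data
#' module. Defaults emulate the real design at desk scale: 165 inbred
#' lines from 8 founders, 12 chromosomes, around 1000 SNPs in total, and
#' an expected 4 observable crossover breakpoints per chromosome per line
#' (an advanced-generation inter-cross accumulates several meioses of
#' recombination beyond a biparental RIL).
#'
#' @param n_lines number of lines.
#' @param n_chroms number of chromosomes.
#' @param n_snps_per_chrom SNPs per chromosome (scalar or length
#'   \code{n_chroms}).
#' @param breakpoint_rate expected breakpoints per chromosome per line.
#' @param noise_sd phenotype noise standard deviation (trait units).
#' @param n_environments number of simulated environments (years).
#' @param seed integer seed; all generator functions draw from a private
#'   stream seeded with it.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_lines = 165L, n_chroms = 12L, n_snps_per_chrom = 84L,
                       breakpoint_rate = 4, noise_sd = 1,
                       n_environments = 2L, seed = 1L) {
  stopifnot(is_count(n_lines), is_count(n_chroms),
            all(vapply(n_snps_per_chrom, is_count, logical(1L))),
            length(n_snps_per_chrom) %in% c(1L, n_chroms),
            breakpoint_rate >= 0, noise_sd >= 0, is_count(n_environments),
            is_count(abs(seed) + 1))
  structure(list(n_lines = as.integer(n_lines),
                 n_chroms = as.integer(n_chroms),
                 n_snps_per_chrom = as.integer(rep_len(n_snps_per_chrom, n_chroms)),
                 breakpoint_rate = breakpoint_rate,
                 noise_sd = noise_sd,
                 n_environments = as.integer(n_environments),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Equally spaced SNP map
#'
#' SNP positions equally spaced along each chromosome (1-based bp,
#' strictly increasing), sorted by (chromosome, position).
#'
#' @param n_chroms number of chromosomes.
#' @param n_snps_per_chrom SNPs per chromosome (scalar or vector).
#' @param chrom_length_bp chromosome length in bp.
#' @return data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos_bp}.
#' @export
make_snp_map <- function(n_chroms = 12L, n_snps_per_chrom = 84L,
                         chrom_length_bp = 30e6) {
  stopifnot(is_count(n_chroms), chrom_length_bp > 1)
  n_snps_per_chrom <- as.integer(rep_len(n_snps_per_chrom, n_chroms))
  maps <- lapply(seq_len(n_chroms), function(ch) {
    n <- n_snps_per_chrom[ch]
    pos <- round(seq(1, chrom_length_bp, length.out = n))
    if (any(diff(pos) <= 0))
      stop("too many SNPs for the chromosome length: positions not strictly increasing")
    data.frame(snp_id = sprintf("c%02d_s%04d", ch, seq_len(n)),
               chrom = ch, pos_bp = pos, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, maps)
  attr(out, "chrom_length_bp") <- chrom_length_bp
  out
}

#' Simulate founder-mosaic genotypes
#'
#' Each line x chromosome is a contiguous mosaic of founder labels: the
#' founder at the chromosome start is drawn uniformly from the 8, crossover
#' breakpoints are placed by a Poisson process with the configured expected
#' count per chromosome (positions uniform along the chromosome, i.e. in
#' interval space, not SNP-index space), and at each breakpoint a new
#' founder is drawn uniformly from the 7 others - so every breakpoint is
#' observable as a label change. Deterministic given \code{cfg$seed}.
#'
#' @param cfg a [sim_config()].
#' @param snp_map SNP map (default [make_snp_map()] from \code{cfg}); must
#'   be sorted by (chrom, pos_bp).
#' @param missing_rate fraction of cells set to \code{NA} at random
#'   (default 0).
#' @return integer matrix \code{n_lines} x \code{n_snps} with values 1..8
#'   (or \code{NA}), rownames \code{L001..}, colnames \code{snp_id};
#'   attribute \code{n_breakpoints} is the lines x chromosomes matrix of
#'   placed crossover counts.
#' @export
gen_founder_mosaic <- function(cfg, snp_map = NULL, missing_rate = 0) {
  stopifnot(inherits(cfg, "sim_config"), missing_rate >= 0, missing_rate < 1)
  if (is.null(snp_map))
    snp_map <- make_snp_map(cfg$n_chroms, cfg$n_snps_per_chrom)
  if (nrow(snp_map) == 0L) stop("empty SNP map")
  o <- order(snp_map$chrom, snp_map$pos_bp)
  if (!identical(o, seq_len(nrow(snp_map))))
    stop("snp_map must be sorted by (chrom, pos_bp)")
  chroms <- unique(snp_map$chrom)
  L <- attr(snp_map, "chrom_length_bp")
  pos_by_chrom <- lapply(chroms, function(ch) snp_map$pos_bp[snp_map$chrom == ch])
  len_by_chrom <- vapply(seq_along(chroms), function(i) {
    if (!is.null(L)) L else max(pos_by_chrom[[i]])
  }, numeric(1L))

  local_seed(cfg$seed, {
    n_snps <- nrow(snp_map)
    haplo <- matrix(NA_integer_, cfg$n_lines, n_snps,
                    dimnames = list(sprintf("L%03d", seq_len(cfg$n_lines)),
                                    snp_map$snp_id))
    nbp <- matrix(0L, cfg$n_lines, length(chroms))
    col0 <- cumsum(c(0L, vapply(pos_by_chrom, length, integer(1L))))
    for (i in seq_len(cfg$n_lines)) {
      for (ci in seq_along(chroms)) {
        pos <- pos_by_chrom[[ci]]
        nb <- stats::rpois(1L, cfg$breakpoint_rate)
        bp <- sort(stats::runif(nb, 0, len_by_chrom[ci]))
        founders <- integer(nb + 1L)
        founders[1L] <- sample.int(8L, 1L)
        if (nb > 0L) for (s in seq_len(nb)) {
          # uniform over the 7 other founders: every crossover is visible
          f <- sample.int(7L, 1L)
          founders[s + 1L] <- f + (f >= founders[s])
        }
        seg <- findInterval(pos, bp) + 1L
        haplo[i, (col0[ci] + 1L):(col0[ci] + length(pos))] <- founders[seg]
        nbp[i, ci] <- nb
      }
    }
    if (missing_rate > 0) {
      drop <- stats::runif(length(haplo)) < missing_rate
      haplo[drop] <- NA_integer_
    }
    attr(haplo, "n_breakpoints") <- nbp
    haplo
  })
}
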