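#' The eight MAGIC founder codes
#'
#' Founder labels 1..8 in the haplotype matrix correspond to the cultivars
#' Akidawara (AK), Bekogonomi (BE), Tachiaoba (TC), Mizuhochikara (MI; all
#' japonica), Suwon 258 (SU), Takanari (TK), Hokuriku 193 (HO) and Ruriaoba
#' (RU; all indica).
#' @export
magic_founders <- c("AK", "BE", "TC", "MI", "SU", "TK", "HO", "RU")

#' Haplotype-based GWAS scan
#'
#' For every SNP, lines are grouped by the founder haplotype they carry and
#' the phenotype is tested across groups with the Kruskal-Wallis rank sum
#' test ([kruskal_wallis()]). Lines with a missing haplotype at a SNP are
#' dropped for that SNP; groups smaller than \code{min_group_size} are
#' dropped; a SNP is tested only if at least \code{min_groups} groups
#' remain (the discard rule for loci segregating for too few haplotypes),
#' otherwise its status is \code{"discarded"}. No genome-wide threshold is
#' applied - peaks are ranked downstream - but a Bonferroni-adjusted
#' p-value column is included for information.
#'
#' @param haplo integer matrix lines x SNPs with founder labels 1..8 or
#'   \code{NA}; rownames are line ids, colnames SNP ids matching
#'   \code{snp_map$snp_id}.
#' @param snp_map data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos_bp}, sorted by (chrom, pos_bp).
#' @param pheno phenotype table: data.frame with columns \code{line_id},
#'   \code{trait}, \code{environment}, \code{value}.
#' @param trait,environment which phenotype slice to scan.
#' @param min_groups minimum surviving haplotype groups for a SNP to be
#'   tested (default 3: loci with only 1 or 2 haplotypes are discarded).
#' @param min_group_size minimum lines per haplotype group (default 2; a
#'   singleton group contributes a degenerate rank mean).
#' @return an object of class \code{gwas_result}: data.frame with one row
#'   per SNP in map order: \code{snp_id}, \code{chrom}, \code{pos_bp},
#'   \code{n_groups}, \code{n_lines}, \code{H}, \code{df}, \code{p},
#'   \code{neglog10p}, \code{p_bonferroni}, \code{status}
#'   (tested/discarded/degenerate).
#' @export
run_gwas <- function(haplo, snp_map, pheno, trait, environment,
                     min_groups = 3L, min_group_size = 2L) {
  stopifnot(is.matrix(haplo), is.data.frame(snp_map),
            all(c("snp_id", "chrom", "pos_bp") %in% names(snp_map)),
            ncol(haplo) == nrow(snp_map),
            is_count(min_groups), min_groups >= 2L, is_count(min_group_size))
  ph <- pheno[pheno$trait == trait & pheno$environment == environment &
                is.finite(pheno$value), , drop = FALSE]
  if (nrow(ph) == 0L)
    stop(sprintf("no phenotype values for trait '%s' in environment '%s'",
                 trait, environment))
  y <- ph$value[match(rownames(haplo), ph$line_id)]
  keep <- !is.na(y)
  if (sum(keep) < min_groups * min_group_size)
    stop("too few phenotyped lines for the configured group constraints")
  y <- y[keep]
  hx <- haplo[keep, , drop = FALSE]
  n_all <- length(y)

  # phenotype ranks / tie term are reusable whenever no line is dropped at a SNP
  r_full <- rank(y)
  tg <- tabulate(match(y, y)); tg <- tg[tg > 0L]
  tie_full <- sum(tg^3 - tg)

  n_snps <- ncol(hx)
  H <- p <- rep(NA_real_, n_snps)
  df <- n_groups <- n_lines <- rep(NA_integer_, n_snps)
  status <- rep("discarded", n_snps)

  for (j in seq_len(n_snps)) {
    g <- hx[, j]
    sizes <- tabulate(g, nbins = 8L)
    founders_kept <- which(sizes >= min_group_size)
    k <- length(founders_kept)
    n_groups[j] <- k
    if (k < min_groups) next
    use <- !is.na(g) & g %in% founders_kept
    gl <- match(g[use], founders_kept)     # relabel groups 1..k
    n_lines[j] <- sum(use)
    res <- if (all(use))
      kw_core(y, gl, k, r = r_full, tie_term = tie_full)
    else
      kw_core(y[use], gl, k)
    H[j] <- res$H; df[j] <- res$df; p[j] <- res$p
    status[j] <- if (res$degenerate) "degenerate" else "tested"
  }
  n_tested <- sum(status == "tested")
  out <- data.frame(snp_id = snp_map$snp_id, chrom = snp_map$chrom,
                    pos_bp = snp_map$pos_bp, n_groups = n_groups,
                    n_lines = n_lines, H = H, df = df, p = p,
                    neglog10p = -log10(p),
                    p_bonferroni = pmin(1, p * n_tested),
                    status = status, stringsAsFactors = FALSE)
  attr(out, "trait") <- trait
  attr(out, "environment") <- environment
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Call peaks in a -log10 p track
#'
#' Candidate peaks are strict interior local maxima (greater than both
#' neighbours; a flat plateau higher than its flanks contributes its
#' leftmost index). Candidates are then selected greedily in order of
#' decreasing height (ties broken towards the left), discarding any
#' candidate closer than \code{min_distance} SNP indices to an
#' already-selected peak, until \code{n_top} peaks are kept. Distances are
#' in SNP-index units, not bp. \code{NA} entries (e.g. discarded SNPs)
#' cannot be peaks and break plateaus.
#'
#' @param track numeric vector (-log10 p in map order).
#' @param min_distance minimum index separation between reported peaks
#'   (default 100).
#' @param n_top maximum number of peaks returned (default 8).
#' @return data.frame with columns \code{index} (1-based position in the
#'   track), \code{height}, \code{rank}; zero rows if the track has no
#'   interior local maximum.
#' @export
find_peaks <- function(track, min_distance = 100L, n_top = 8L) {
  stopifnot(is.numeric(track) || all(is.na(track)),
            is_count(min_distance), is_count(n_top))
  empty <- data.frame(index = integer(0), height = numeric(0), rank = integer(0))
  n <- length(track)
  if (n < 3L) return(empty)
  x <- as.numeric(track)
  x[!is.finite(x)] <- -Inf
  runs <- rle(x)
  k <- length(runs$values)
  if (k < 3L) return(empty)
  starts <- cumsum(c(1L, runs$lengths[-k]))
  v <- runs$values
  is_peak <- c(FALSE, v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k], FALSE) &
    is.finite(v)
  idx <- starts[is_peak]
  h <- v[is_peak]
  if (length(idx) == 0L) return(empty)

  ord <- order(-h, idx)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= n_top) break
    if (all(abs(idx[i] - idx[sel]) >= min_distance)) sel <- c(sel, i)
  }
  out <- data.frame(index = idx[sel], height = h[sel],
                    rank = seq_along(sel))
  out[order(out$rank), , drop = FALSE]
}

#' Call QTL peaks from a GWAS result
#'
#' Runs [find_peaks()] on the -log10 p track of a [run_gwas()] result and
#' annotates the called peaks with SNP id, chromosome and position.
#'
#' @param gwas a \code{gwas_result}.
#' @inheritParams find_peaks
#' @return data.frame: \code{rank}, \code{snp_id}, \code{chrom},
#'   \code{pos_bp}, \code{index}, \code{neglog10p}.
#' @export
call_qtl_peaks <- function(gwas, min_distance = 100L, n_top = 8L) {
  stopifnot(inherits(gwas, "gwas_result"))
  pk <- find_peaks(gwas$neglog10p, min_distance, n_top)
  data.frame(rank = pk$rank,
             snp_id = gwas$snp_id[pk$index],
             chrom = gwas$chrom[pk$index],
             pos_bp = gwas$pos_bp[pk$index],
             index = pk$index,
             neglog10p = pk$height,
             stringsAsFactors = FALSE)
}

#' Founder haplotype effects at one SNP
#'
#' Mean phenotype of the lines carrying each founder haplotype at a SNP -
#' the length-8 effect vector behind the haplotype-effect scatter plots.
#' Founders carried by no line get \code{NA}. If fewer than
#' \code{min_groups} founders are represented (the 1-or-2-haplotype discard
#' rule), the whole vector is returned all-\code{NA} and flagged discarded.
#'
#' @inheritParams run_gwas
#' @param snp_id which SNP.
#' @param min_groups minimum founder groups for the vector to be defined.
#' @return named numeric vector of length 8 (names [magic_founders]), with
#'   attributes \code{n} (group sizes) and \code{discarded}.
#' @export
haplotype_effects <- function(haplo, snp_map, pheno, trait, environment,
                              snp_id, min_groups = 3L) {
  j <- match(snp_id, snp_map$snp_id)
  if (is.na(j)) stop(sprintf("unknown snp_id '%s'", snp_id))
  ph <- pheno[pheno$trait == trait & pheno$environment == environment &
                is.finite(pheno$value), , drop = FALSE]
  y <- ph$value[match(rownames(haplo), ph$line_id)]
  g <- haplo[, j]
  use <- !is.na(y) & !is.na(g)
  sizes <- tabulate(g[use], nbins = 8L)
  eff <- rep(NA_real_, 8L)
  present <- which(sizes > 0L)
  for (f in present) eff[f] <- mean(y[use][g[use] == f])
  names(eff) <- magic_founders
  discarded <- length(present) < min_groups
  if (discarded) eff[] <- NA_real_
  structure(eff, n = stats::setNames(sizes, magic_founders),
            discarded = discarded)
}

#' Pearson correlation between two founder effect vectors
#'
#' Correlates two length-8 effect vectors (e.g. the same QTL in two years,
#' or two traits at one QTL) over pairwise-complete founders, with a
#' two-sided p-value from the t transform on \code{n_used - 2} degrees of
#' freedom and the significance tiers ** p<0.01, * p<0.05, + p<0.1.
#'
#' @param x,y numeric vectors of length 8 (entries may be \code{NA}).
#' @return list with \code{r}, \code{p}, \code{n_used}, \code{tier},
#'   \code{flagged} (TRUE when fewer than 3 complete pairs, or a constant
#'   vector makes r undefined).
#' @export
effect_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L)
    return(list(r = NA_real_, p = NA_real_, n_used = n,
                tier = NA_character_, flagged = TRUE))
  xs <- x[ok] - mean(x[ok]); ys <- y[ok] - mean(y[ok])
  sx <- sum(xs^2); sy <- sum(ys^2)
  if (sx == 0 || sy == 0)
    return(list(r = NA_real_, p = NA_real_, n_used = n,
                tier = NA_character_, flagged = TRUE))
  r <- sum(xs * ys) / sqrt(sx * sy)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(r = r, p = p, n_used = n, tier = signif_tier(p), flagged = FALSE)
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("gwas_result: %s @ %s, %d SNPs (%d tested, %d discarded), max -log10p %.2f\n",
              attr(x, "trait"), attr(x, "environment"), nrow(x),
              sum(x$status == "tested"), sum(x$status == "discarded"),
              suppressWarnings(max(x$neglog10p, na.rm = TRUE))))
  invisible(x)
}
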