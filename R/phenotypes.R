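#' Specification of one simulated QTL
#'
#' A causal SNP together with the additive effect (in phenotype units) of
#' each of the 8 founder haplotypes at it.
#'
#' @param snp_index 1-based index into the SNP map.
#' @param effects numeric vector of exactly 8 per-founder effects.
#' @return list of class \code{qtl_spec}.
#' @export
qtl_spec <- function(snp_index, effects) {
  stopifnot(is_count(snp_index), is.numeric(effects), length(effects) == 8L,
            all(is.finite(effects)))
  structure(list(snp_index = as.integer(snp_index),
                 effects = as.numeric(effects)),
            class = "qtl_spec")
}

#' Simulate phenotypes from planted QTL effects
#'
#' Phenotype of line i in every environment =
#' baseline + sum over QTLs of the effect of the founder haplotype the
#' line carries at the causal SNP + independent Gaussian noise
#' (sd = \code{noise_sd}). The genetic part is identical across
#' environments and only the noise differs, mirroring a two-year design
#' with year-stable haplotype effects. Lines with a missing haplotype at a
#' causal SNP get \code{NA}.
#'
#' @param haplo haplotype matrix from [gen_founder_mosaic()].
#' @param qtls list of [qtl_spec()] objects (possibly empty: pure noise).
#' @param noise_sd noise standard deviation (>= 0).
#' @param n_environments number of environments.
#' @param seed integer seed for the private noise stream.
#' @param trait trait name recorded in the table (default \code{"SDW"}).
#' @param baseline additive constant (trait units).
#' @param environments environment labels (default \code{"Y1"}, ...).
#' @return long-format data.frame: \code{line_id}, \code{trait},
#'   \code{environment}, \code{value}.
#' @export
gen_phenotypes <- function(haplo, qtls = list(), noise_sd, n_environments = 2L,
                           seed = 1L, trait = "SDW", baseline = 0,
                           environments = NULL) {
  stopifnot(is.matrix(haplo), is.list(qtls))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("noise_sd must be a single non-negative number")
  stopifnot(is_count(n_environments))
  if (is.null(environments)) environments <- sprintf("Y%d", seq_len(n_environments))
  stopifnot(length(environments) == n_environments)

  n <- nrow(haplo)
  genetic <- rep(baseline, n)
  for (q in qtls) {
    stopifnot(inherits(q, "qtl_spec"))
    if (q$snp_index > ncol(haplo)) stop("qtl snp_index outside the SNP map")
    genetic <- genetic + q$effects[haplo[, q$snp_index]]
  }
  local_seed(seed, {
    do.call(rbind, lapply(seq_len(n_environments), function(e) {
      data.frame(line_id = rownames(haplo), trait = trait,
                 environment = environments[e],
                 value = genetic + stats::rnorm(n, 0, noise_sd),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Noise level for a target heritability at one QTL
#'
#' Returns the noise standard deviation such that the genetic values of
#' the QTL explain a fraction \code{h2} of total phenotypic variance in
#' this population: \code{sd = sqrt(var_g * (1 - h2) / h2)} with
#' \code{var_g} the variance of the planted genetic values across lines.
#'
#' @param haplo haplotype matrix.
#' @param qtl a [qtl_spec()].
#' @param h2 target fraction of variance explained, in (0, 1).
#' @export
calibrate_noise_sd <- function(haplo, qtl, h2) {
  stopifnot(inherits(qtl, "qtl_spec"), h2 > 0, h2 < 1)
  g <- qtl$effects[haplo[, qtl$snp_index]]
  var_g <- stats::var(g, na.rm = TRUE)
  if (!is.finite(var_g) || var_g == 0)
    stop("QTL explains no variance in this population (constant genetic values)")
  sqrt(var_g * (1 - h2) / h2)
}
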