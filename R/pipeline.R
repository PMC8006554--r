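#' Configuration for a full synthetic pipeline run
#'
#' Collects every tunable of the simulate -> image -> segment -> score ->
#' GWAS chain. The defaults give a desk-scale run: 60 lines genotyped at
#' 480 SNPs on 12 chromosomes, imaged at the half-scale layout (4 mm/px)
#' in two environments, with one vegetation-cover QTL and one
#' architecture (spread) QTL planted unless \code{null_run = TRUE}.
#' Because the default map is ~28x sparser than a real genotyping-by-
#' sequencing map, the peak-separation window defaults to 20 SNP indices
#' rather than the 100 used at full marker density.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_lines,n_chroms,n_snps_per_chrom,breakpoint_rate population and
#'   genome size (see [sim_config()]).
#' @param layout imaging layout (see [plot_layout()]).
#' @param n_environments simulated years.
#' @param base_cover mean true cover fraction at the plot scale.
#' @param cover_effect_sd,spread_effect_sd SD of the planted per-founder
#'   QTL effects on cover (fraction) and spread (dimensionless).
#' @param cover_env_shift additive cover shift per environment (recycled).
#' @param cover_noise_sd,spread_noise_sd per line x environment noise.
#' @param sdw_per_cover,sdw_noise_sd linear map from true cover to shoot
#'   dry weight (g DW per plant) and its residual SD.
#' @param null_run if TRUE, no QTLs are planted (pure-noise benchmark).
#' @param min_groups,min_group_size,min_distance,n_top GWAS options.
#' @param tile_side_px,shape_mode AT options.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, n_lines = 60L, n_chroms = 12L,
                            n_snps_per_chrom = 40L, breakpoint_rate = 4,
                            layout = plot_layout_half(),
                            n_environments = 2L,
                            base_cover = 0.25,
                            cover_effect_sd = 0.06, spread_effect_sd = 0.18,
                            cover_env_shift = c(0, 0.03),
                            cover_noise_sd = 0.02, spread_noise_sd = 0.05,
                            sdw_per_cover = 28, sdw_noise_sd = 2.0,
                            null_run = FALSE,
                            min_groups = 3L, min_group_size = 2L,
                            min_distance = 20L, n_top = 5L,
                            tile_side_px = NULL, shape_mode = "square-annuli") {
  stopifnot(inherits(layout, "plot_layout"), is_count(n_environments))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic phenotyping + GWAS pipeline
#'
#' Executes all stages on simulated data: founder-mosaic genotypes, true
#' cover/spread/shoot-weight phenotypes driven by planted QTL effects,
#' scene rendering, strip composition and plot re-extraction, a*/Otsu
#' segmentation (measured VF), archery-target scoring (measured AT), the
#' haplotype-based Kruskal-Wallis scan per trait and environment, QTL peak
#' calling, founder effect vectors at the top peaks and their
#' between-year correlations, and VF-SDW trait correlations. With a fixed
#' seed the run (and the summary JSON it writes) is fully deterministic.
#'
#' @param config a [pipeline_config()].
#' @param out_dir if non-NULL, per-stage tables, a copy of the config, a
#'   wall-time log and \code{summary.json} are written there.
#' @param make_figures write Manhattan, distribution and scatter figures
#'   under \code{out_dir/figures} (requires \code{out_dir}).
#' @return a \code{pipeline_report}: list with \code{summary} (what
#'   \code{summary.json} holds), \code{phenotypes}, \code{truth},
#'   \code{gwas} (per trait x environment), \code{peaks}, \code{effects},
#'   \code{haplo}, \code{snp_map}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         make_figures = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (make_figures && is.null(out_dir)) stop("figures require out_dir")
  t_log <- list(); tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  envs <- sprintf("Y%d", seq_len(config$n_environments))
  shift <- rep_len(config$cover_env_shift, config$n_environments)

  ## stage 1: genotypes and planted QTLs -----------------------------------
  cfg <- sim_config(n_lines = config$n_lines, n_chroms = config$n_chroms,
                    n_snps_per_chrom = config$n_snps_per_chrom,
                    breakpoint_rate = config$breakpoint_rate,
                    n_environments = config$n_environments,
                    seed = config$seed + 1L)
  snp_map <- make_snp_map(config$n_chroms, config$n_snps_per_chrom)
  haplo <- gen_founder_mosaic(cfg, snp_map)
  n_snps <- nrow(snp_map)

  mid_snp <- function(chrom) {
    idx <- which(snp_map$chrom == chrom)
    idx[ceiling(length(idx) / 2)]
  }
  qtls <- list()
  if (!config$null_run) {
    vf_chrom <- max(1L, ceiling(config$n_chroms * 0.75))
    at_chrom <- min(config$n_chroms, 3L)
    eff <- local_seed(config$seed + 2L, list(
      cover = stats::rnorm(8L, 0, config$cover_effect_sd),
      spread = stats::rnorm(8L, 0, config$spread_effect_sd)))
    qtls <- list(cover = qtl_spec(mid_snp(vf_chrom), eff$cover),
                 spread = qtl_spec(mid_snp(at_chrom), eff$spread))
  }
  t_log$simulate_genotypes <- tic() - t0; t0 <- tic()

  ## stage 2: true phenotypes per line x environment -----------------------
  n <- config$n_lines
  lines <- rownames(haplo)
  cover_g <- rep(config$base_cover, n)
  spread_g <- rep(0.5, n)
  if (!config$null_run) {
    cover_g <- cover_g + qtls$cover$effects[haplo[, qtls$cover$snp_index]]
    spread_g <- spread_g + qtls$spread$effects[haplo[, qtls$spread$snp_index]]
  }
  truth <- local_seed(config$seed + 3L, {
    do.call(rbind, lapply(seq_along(envs), function(e) {
      cover <- pmin(0.55, pmax(0.06,
        cover_g + shift[e] + stats::rnorm(n, 0, config$cover_noise_sd)))
      spread <- pmin(0.95, pmax(0.05,
        spread_g + stats::rnorm(n, 0, config$spread_noise_sd)))
      sdw <- config$sdw_per_cover * cover +
        stats::rnorm(n, 0, config$sdw_noise_sd)
      data.frame(line_id = lines, environment = envs[e],
                 cover = cover, spread = spread, sdw = sdw,
                 stringsAsFactors = FALSE)
    }))
  })
  t_log$simulate_phenotypes <- tic() - t0; t0 <- tic()

  ## stage 3: imaging, strip composition, extraction, VF + AT --------------
  lay <- config$layout
  tile <- if (is.null(config$tile_side_px)) default_tile_side(lay)
          else config$tile_side_px
  strip_size <- 6L
  pheno_rows <- vector("list", nrow(truth))
  sample_strip <- NULL
  for (e in seq_along(envs)) {
    rows_e <- which(truth$environment == envs[e])
    batches <- split(rows_e, (seq_along(rows_e) - 1L) %/% strip_size)
    for (b in batches) {
      scenes <- lapply(seq_along(b), function(i) {
        r <- truth[b[i], ]
        gen_canopy_scene(lay, coverage_target = r$cover, spread = r$spread,
                         seed = config$seed + 100000L * e + b[i])
      })
      strip <- array(0L, c(lay$plot_height_px,
                           lay$plot_width_px * length(b), 3L))
      for (i in seq_along(b)) {
        c0 <- (i - 1L) * lay$plot_width_px
        strip[, (c0 + 1L):(c0 + lay$plot_width_px), ] <- scenes[[i]]$image
      }
      grid <- stats::setNames(lapply(seq_along(b) - 1L, function(j) c(0L, j)),
                              truth$line_id[b])
      slay <- plot_layout(lay$plot_width_px, lay$plot_height_px,
                          lay$plant_spacing_px, lay$row_spacing_px,
                          lay$resolution_mm_per_px, grid = grid)
      if (is.null(sample_strip)) sample_strip <- strip
      for (i in seq_along(b)) {
        region <- extract_plot_region(strip, slay, truth$line_id[b[i]])
        vf <- measure_vf(region$image)
        at <- measure_at(vf$mask, lay, tile, config$shape_mode)
        r <- truth[b[i], ]
        pheno_rows[[b[i]]] <- data.frame(
          line_id = rep(r$line_id, 3L), trait = c("VF", "AT", "SDW"),
          environment = rep(envs[e], 3L),
          value = c(vf$vf, at$at, r$sdw), stringsAsFactors = FALSE)
      }
    }
  }
  pheno <- do.call(rbind, pheno_rows)
  rownames(pheno) <- NULL
  t_log$image_and_score <- tic() - t0; t0 <- tic()

  ## stage 4: GWAS per trait x environment, peaks, effects -----------------
  traits <- c("VF", "AT", "SDW")
  gwas <- list(); peaks <- list(); effects <- list()
  for (tr in traits) for (ev in envs) {
    key <- paste(tr, ev, sep = "_")
    g <- run_gwas(haplo, snp_map, pheno, tr, ev,
                  min_groups = config$min_groups,
                  min_group_size = config$min_group_size)
    gwas[[key]] <- g
    peaks[[key]] <- call_qtl_peaks(g, config$min_distance, config$n_top)
  }
  top_index <- function(key) {
    pk <- peaks[[key]]
    if (nrow(pk) == 0L) NA_integer_ else pk$index[1L]
  }
  effect_at <- function(tr, ev, idx) {
    if (is.na(idx)) return(NULL)
    haplotype_effects(haplo, snp_map, pheno, tr, ev, snp_map$snp_id[idx],
                      min_groups = config$min_groups)
  }
  # between-year effect correlation at each trait's first-year top peak
  eff_cor <- list()
  stability <- list()
  for (tr in traits) {
    k1 <- paste(tr, envs[1L], sep = "_")
    idx1 <- top_index(k1)
    for (ev in envs) effects[[paste(tr, ev, sep = "_")]] <-
      effect_at(tr, ev, idx1)
    if (length(envs) >= 2L) {
      k2 <- paste(tr, envs[2L], sep = "_")
      e1 <- effects[[k1]]; e2 <- effects[[k2]]
      eff_cor[[tr]] <- if (is.null(e1) || is.null(e2))
        list(r = NA_real_, p = NA_real_, n_used = 0L,
             tier = NA_character_, flagged = TRUE)
      else effect_correlation(as.numeric(e1), as.numeric(e2))
      idx2 <- top_index(k2)
      stability[[tr]] <- list(
        top_index = stats::setNames(as.list(c(idx1, idx2)), envs[1:2]),
        stable = !is.na(idx1) && !is.na(idx2) &&
          abs(idx1 - idx2) < config$min_distance)
    }
  }
  # trait correlations (VF vs SDW per environment)
  wide <- function(tr, ev) {
    s <- pheno[pheno$trait == tr & pheno$environment == ev, ]
    s$value[match(lines, s$line_id)]
  }
  vf_sdw <- lapply(envs, function(ev) {
    ct <- stats::cor.test(wide("VF", ev), wide("SDW", ev))
    list(r = unname(ct$estimate), p = ct$p.value,
         tier = signif_tier(ct$p.value))
  })
  names(vf_sdw) <- envs
  t_log$gwas <- tic() - t0; t0 <- tic()

  ## summary ---------------------------------------------------------------
  planted <- if (config$null_run) NULL else
    list(cover = list(snp_id = snp_map$snp_id[qtls$cover$snp_index],
                      index = qtls$cover$snp_index),
         spread = list(snp_id = snp_map$snp_id[qtls$spread$snp_index],
                       index = qtls$spread$snp_index))
  top_peaks <- lapply(peaks, function(pk) {
    if (nrow(pk) == 0L) return(list())
    lapply(seq_len(nrow(pk)), function(i)
      list(rank = pk$rank[i], snp_id = pk$snp_id[i], chrom = pk$chrom[i],
           pos_bp = pk$pos_bp[i], index = pk$index[i],
           neglog10p = pk$neglog10p[i]))
  })
  recovery <- NULL
  if (!config$null_run) {
    d_idx <- function(tr, causal) {
      i <- top_index(paste(tr, envs[1L], sep = "_"))
      if (is.na(i)) NA_integer_ else abs(i - causal)
    }
    recovery <- list(vf_top_peak_dist = d_idx("VF", qtls$cover$snp_index),
                     at_top_peak_dist = d_idx("AT", qtls$spread$snp_index),
                     sdw_top_peak_dist = d_idx("SDW", qtls$cover$snp_index))
  }
  summary <- list(
    seed = config$seed,
    sizes = list(n_lines = config$n_lines, n_snps = n_snps,
                 n_chroms = config$n_chroms,
                 n_environments = config$n_environments,
                 plot_px = c(lay$plot_height_px, lay$plot_width_px),
                 tile_side_px = tile),
    null_run = config$null_run,
    planted_qtls = planted,
    trait_summary = lapply(stats::setNames(traits, traits), function(tr)
      lapply(stats::setNames(envs, envs), function(ev) {
        v <- wide(tr, ev)
        list(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v))
      })),
    top_peaks = top_peaks,
    recovery = recovery,
    effect_correlation_year1_vs_year2 = eff_cor,
    peak_stability = stability,
    vf_sdw_correlation = vf_sdw)

  report <- structure(list(summary = summary, phenotypes = pheno,
                           truth = truth, gwas = gwas, peaks = peaks,
                           effects = effects, haplo = haplo,
                           snp_map = snp_map, config = config,
                           sample_strip = sample_strip),
                      class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_haplotypes(haplo, file.path(out_dir, "haplotypes.tsv"))
    write_snp_map(snp_map, file.path(out_dir, "snp_map.tsv"))
    write_phenotypes(pheno, file.path(out_dir, "phenotypes.csv"))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    for (key in names(gwas)) {
      utils::write.table(gwas[[key]], file.path(out_dir, sprintf("gwas_%s.tsv", key)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(peaks[[key]], file.path(out_dir, sprintf("peaks_%s.tsv", key)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    cfg_out <- config; cfg_out$layout <- unclass(cfg_out$layout)
    jsonlite::write_json(unclass(cfg_out), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    t_log$write_outputs <- tic() - t0
    writeLines(c(sprintf("pipeline run, seed %d", config$seed),
                 sprintf("%-22s %8.2f s", names(t_log), unlist(t_log))),
               file.path(out_dir, "log.txt"))
    if (make_figures) pipeline_figures(report, file.path(out_dir, "figures"))
  }
  invisible(report)
}

#' Manhattan plot of a GWAS result
#'
#' Base-graphics Manhattan plot of the -log10 p track in map order, with
#' chromosomes in alternating shades and called peaks marked.
#'
#' @param gwas a \code{gwas_result}.
#' @param peaks optional peak table from [call_qtl_peaks()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_manhattan <- function(gwas, peaks = NULL, ...) {
  stopifnot(inherits(gwas, "gwas_result"))
  col <- c("grey25", "steelblue")[gwas$chrom %% 2L + 1L]
  graphics::plot(seq_len(nrow(gwas)), gwas$neglog10p, col = col, pch = 16,
                 cex = 0.5, xlab = "SNP index (map order)",
                 ylab = expression(-log[10] * italic(P)),
                 main = sprintf("%s @ %s", attr(gwas, "trait"),
                                attr(gwas, "environment")), ...)
  if (!is.null(peaks) && nrow(peaks) > 0L)
    graphics::points(peaks$index, peaks$neglog10p, col = "red", pch = 1, cex = 1.6)
  invisible(NULL)
}

# distribution panels, VF-SDW scatter, Manhattan + effect plots
pipeline_figures <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- report$phenotypes
  envs <- unique(ph$environment)
  traits <- unique(ph$trait)

  grDevices::png(file.path(dir, "trait_distributions.png"), 1200, 800, res = 120)
  graphics::par(mfrow = c(length(envs), length(traits)), mar = c(4, 4, 2, 1))
  for (ev in envs) for (tr in traits) {
    v <- ph$value[ph$trait == tr & ph$environment == ev]
    graphics::hist(v, breaks = 20, col = "darkseagreen3", border = "white",
                   main = sprintf("%s @ %s", tr, ev), xlab = tr)
  }
  grDevices::dev.off()

  grDevices::png(file.path(dir, "vf_vs_sdw.png"), 900, 500, res = 120)
  graphics::par(mfrow = c(1, length(envs)), mar = c(4, 4, 2, 1))
  for (ev in envs) {
    vf <- ph$value[ph$trait == "VF" & ph$environment == ev]
    sdw <- ph$value[ph$trait == "SDW" & ph$environment == ev]
    graphics::plot(vf, sdw, pch = 16, col = "grey30",
                   xlab = "VF (%)", ylab = "SDW (g DW/plant)",
                   main = sprintf("%s: r = %.2f", ev, stats::cor(vf, sdw)))
    graphics::abline(stats::lm(sdw ~ vf), col = "red")
  }
  grDevices::dev.off()

  for (key in names(report$gwas)) {
    grDevices::png(file.path(dir, sprintf("manhattan_%s.png", key)), 1100, 420,
                   res = 120)
    plot_manhattan(report$gwas[[key]], report$peaks[[key]])
    grDevices::dev.off()
  }

  for (key in names(report$effects)) {
    eff <- report$effects[[key]]
    if (is.null(eff) || all(is.na(eff))) next
    grDevices::png(file.path(dir, sprintf("effects_%s.png", key)), 700, 500,
                   res = 120)
    graphics::plot(seq_len(8L), as.numeric(eff), pch = 16, cex = 1.4,
                   xaxt = "n", xlab = "founder haplotype",
                   ylab = "mean phenotype", main = key)
    graphics::axis(1, at = seq_len(8L), labels = names(eff))
    grDevices::dev.off()
  }
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("pipeline_report: %d lines x %d SNPs, %d environment(s), seed %d%s\n",
              s$sizes$n_lines, s$sizes$n_snps, s$sizes$n_environments,
              s$seed, if (s$null_run) " (null run)" else ""))
  for (tr in names(s$effect_correlation_year1_vs_year2)) {
    ec <- s$effect_correlation_year1_vs_year2[[tr]]
    cat(sprintf("  %s: effect r(Y1,Y2) = %s%s, top-peak stable: %s\n", tr,
                if (is.na(ec$r)) "NA" else sprintf("%.2f", ec$r),
                if (is.na(ec$tier) || ec$tier == "") "" else ec$tier,
                s$peak_stability[[tr]]$stable))
  }
  invisible(x)
}
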