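#!/usr/bin/env Rscript
# Stage 1: simulate the study population and example canopy scenes.
#
# Generates the synthetic MAGIC population at the study scale (165 lines,
# 12 chromosomes, 1008 SNPs, expected 4 crossovers per chromosome) and two
# example plot scenes - a compact (upright) and a spreading line at equal
# ground cover - then writes everything under results/01_simulate/.

suppressPackageStartupMessages(library(canopygwas))
out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)
map <- make_snp_map(cfg$n_chroms, cfg$n_snps_per_chrom)
haplo <- gen_founder_mosaic(cfg, map)
write_haplotypes(haplo, file.path(out, "haplotypes.tsv"))
write_snp_map(map, file.path(out, "snp_map.tsv"))

freq <- rowMeans(apply(haplo, 2, tabulate, nbins = 8)) / nrow(haplo)
cat("founder frequencies across SNPs (expect ~0.125 each):\n")
print(round(setNames(freq, magic_founders), 4))
cat(sprintf("mean breakpoints per chromosome per line: %.2f (configured %.1f)\n",
            mean(attr(haplo, "n_breakpoints")), cfg$breakpoint_rate))

q <- qtl_spec(500, c(-1.0, -0.6, -0.2, 0, 0.2, 0.6, 1.0, 1.4))
nsd <- calibrate_noise_sd(haplo, q, 0.2)
pheno <- gen_phenotypes(haplo, list(q), nsd, n_environments = 2, seed = 2,
                        baseline = 8)
write_phenotypes(pheno, file.path(out, "phenotypes.csv"))
cat(sprintf("planted QTL at %s; noise sd %.3f targets 20%% explained variance\n",
            map$snp_id[500], nsd))

lay <- plot_layout()
for (sc in list(list(id = "compact_line", spread = 0.15),
                list(id = "spreading_line", spread = 0.85))) {
  scene <- gen_canopy_scene(lay, coverage_target = 0.30, spread = sc$spread,
                            seed = 11)
  write_scene(scene, out, sc$id)
  cat(sprintf("scene %-15s spread %.2f -> truth VF %.3f (target 0.30)\n",
              sc$id, sc$spread, scene$truth_vf))
}
cat("stage 1 outputs in", out, "\n")
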