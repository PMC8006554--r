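# canopygwas

High-throughput field phenotyping of rice from low-altitude RGB imagery,
connected to genetics: **vegetation fraction** (VF) as a proxy for shoot
biomass, an **archery-target** (AT) score for plant architecture, and a
**haplotype-based GWAS** over an 8-founder MAGIC population — with a
synthetic-data module (canopy scenes, founder-mosaic genotypes, QTL-driven
phenotypes) supplying every input with known ground truth, so the whole
chain runs and is testable on a desk.

It is aimed at plant-phenotyping and quantitative-genetics researchers who
want a transparent, fully reproducible reference implementation of this
analysis style: every stage is an ordinary R function, every default is
documented, and every simulated input carries its truth alongside.

## The methods in brief

**VF.** A plot region (450 × 270 px at 2 mm/px, covering 3 × 3 plants) is
converted from sRGB to CIELAB; the a\* (green–red) channel is rescaled to
8 bits and thresholded with Otsu's method (exhaustive search, exact-integer
between-class variance, midpoint tie rule). Plant = the low-a\* class, and

VF = 100 · n_plant / n_total  (% of plot pixels).

**AT.** The nine per-plant tiles of the VF mask are averaged into a mean
mask *P*, partitioned into five concentric regions a…e weighted 1…5 from
outside to centre:

AT = Σᵢ wᵢ · P̄ᵢ / P̄_all ,

so a uniform canopy scores exactly 15, upright/compact habit scores
higher, spreading habit lower (bounds 25 and 5 on equal-area geometry).

**Haplotype GWAS.** At each SNP, lines are grouped by the founder label
they carry (AK, BE, TC, MI, SU, TK, HO, RU) and the phenotype is tested
with the tie-corrected Kruskal–Wallis statistic

H = [12/(N(N+1))] Σ nᵢ (r̄ᵢ − (N+1)/2)² ÷ (1 − Σ(t³−t)/(N³−N)),

with χ²(k−1) p-values; SNPs segregating for fewer than 3 haplotypes are
discarded. QTLs are strict local maxima of the −log₁₀P track selected
greedily with a minimum separation of 100 SNP indices; per-founder effect
vectors at the peaks are compared across traits and years by Pearson
correlation, and allele-class contrasts use the pooled-variance Student's
t-test.

## Worked example

```r
library(canopygwas)

lay <- plot_layout()   # 450 x 270 px, 3 x 3 plants, 2 mm/px
for (sp in c(0.15, 0.85)) {                      # compact vs spreading
  sc <- gen_canopy_scene(lay, coverage_target = 0.30, spread = sp, seed = 11)
  vf <- measure_vf(sc$image)                     # a* -> Otsu -> VF
  at <- measure_at(vf$mask, lay)                 # 9 tiles -> AT
  cat(sprintf("spread %.2f: truth VF %.2f%%, measured VF %.2f%%, a* threshold %.1f, AT %.2f\n",
              sp, 100 * sc$truth_vf, vf$vf, vf$threshold_astar, at$at))
}
#> spread 0.15: truth VF 30.00%, measured VF 30.00%, a* threshold -19.7, AT 21.11
#> spread 0.85: truth VF 29.76%, measured VF 29.76%, a* threshold -19.7, AT 9.52
```

Both plots hold ~30% ground cover, and segmentation recovers the truth to
the second decimal; the AT score separates the compact plant (21.1, well
above the uniform-canopy value 15) from the spreading one (9.5).

```r
cfg   <- sim_config(seed = 1)                    # 165 lines, 12 chrom, 1008 SNPs
map   <- make_snp_map(cfg$n_chroms, cfg$n_snps_per_chrom)
haplo <- gen_founder_mosaic(cfg, map)
qtl   <- qtl_spec(500, c(-1.0, -0.6, -0.2, 0, 0.2, 0.6, 1.0, 1.4))
noise <- calibrate_noise_sd(haplo, qtl, 0.2)     # QTL explains ~20% of variance
pheno <- gen_phenotypes(haplo, list(qtl), noise, n_environments = 2,
                        seed = 2, baseline = 8)

gwas  <- run_gwas(haplo, map, pheno, "SDW", "Y1")
call_qtl_peaks(gwas, min_distance = 100, n_top = 3)
#>   rank    snp_id chrom   pos_bp index neglog10p
#> 1    1 c06_s0081     6 28915663   501  4.741268
#> 2    2 c03_s0001     3        1   169  1.705207
#> 3    3 c09_s0001     9        1   673  1.624857

round(haplotype_effects(haplo, map, pheno, "SDW", "Y1", "c06_s0081"), 2)
#>   AK   BE   TC   MI   SU   TK   HO   RU
#> 6.61 7.71 7.65 8.81 8.05 8.45 9.36 9.17
```

The planted QTL (index 500) is recovered as the rank-1 peak one index
away, with nothing comparable elsewhere in the genome, and the estimated
founder effects track the planted gradient (−1.0 … +1.4 around the
baseline of 8 g).

The numbered drivers under `analysis/` run the full narrative —
`01_simulate.R` (population + example scenes), `02_segment_score.R` (VF
recovery and AT-vs-habit tables), `03_gwas.R` (study-scale scan, peaks,
effect stability across years), `04_report.R` (the end-to-end
`run_pipeline()` with figures) — writing tables and figures under
`results/`.

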