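test_that("canopy scenes honour the coverage contract and determinism", {
  lay <- layout_small()
  s0 <- gen_canopy_scene(lay, 0, 0.5, seed = 3)
  expect_true(all(s0$truth_mask == 0L))
  expect_equal(s0$truth_vf, 0)
  expect_equal(dim(s0$image), c(45L, 75L, 3L))

  s <- gen_canopy_scene(lay, 0.5, 0.4, seed = 1)
  expect_equal(s$truth_vf, mean(s$truth_mask))    # invariant, not a tolerance
  expect_true(s$truth_vf >= 0.47 && s$truth_vf <= 0.53)
  expect_identical(dim(s$image)[1:2], dim(s$truth_mask))

  # bit-identical regeneration under the same seed; different otherwise
  expect_identical(gen_canopy_scene(lay, 0.5, 0.4, seed = 1), s)
  expect_false(identical(gen_canopy_scene(lay, 0.5, 0.4, seed = 2)$image, s$image))

  expect_error(gen_canopy_scene(lay, 0.9, 0.5, seed = 1), "0, 0.8")
  expect_error(gen_canopy_scene(lay, 0.5, 1.4, seed = 1), "spread")
})

test_that("scene colours separate plant and soil on the a* axis", {
  s <- gen_canopy_scene(layout_small(), 0.35, 0.5, seed = 11)
  a <- rgb_to_astar(s$image)
  plant_a <- a[s$truth_mask == 1L]
  soil_a <- a[s$truth_mask == 0L]
  expect_lt(max(plant_a), 0)        # green side
  expect_gt(min(soil_a), -5)        # soil near zero/positive
  expect_gt(min(soil_a) - max(plant_a), 5)   # clear bimodal gap
})

test_that("founder mosaics have the configured block structure", {
  map <- make_snp_map(2, 50)
  # no recombination: one founder per line x chromosome
  h0 <- gen_founder_mosaic(sim_config(n_lines = 30, n_chroms = 2,
                                      n_snps_per_chrom = 50,
                                      breakpoint_rate = 0, seed = 4), map)
  for (ch in 1:2) {
    sub <- h0[, map$chrom == ch]
    expect_true(all(apply(sub, 1, function(r) length(unique(r)) == 1L)))
  }
  expect_equal(dim(h0), c(30L, 100L))
  expect_true(all(h0 %in% 1:8))

  # shape contract at the study scale
  h <- gen_founder_mosaic(sim_config(seed = 5))
  expect_equal(dim(h), c(165L, 12L * 84L))

  # determinism
  expect_identical(gen_founder_mosaic(sim_config(seed = 5)), h)

  expect_error(gen_founder_mosaic(sim_config(seed = 1), map[0, ]), "empty")
  expect_error(gen_founder_mosaic(sim_config(seed = 1),
                                  map[c(51:100, 1:50), ]), "sorted")
})

test_that("per-SNP founder frequencies and breakpoint counts match expectation", {
  cfg <- sim_config(n_lines = 800, n_chroms = 2, n_snps_per_chrom = 10,
                    breakpoint_rate = 3, seed = 6)
  h <- gen_founder_mosaic(cfg)
  # each founder frequency ~ 1/8 within 3 binomial SEs
  se <- sqrt((1 / 8) * (7 / 8) / 800)
  for (j in c(1, 5, 10, 15, 20)) {
    freq <- tabulate(h[, j], 8) / 800
    expect_true(all(abs(freq - 1 / 8) <= 3 * se + 1e-12))
  }
  # realized breakpoints per chromosome per line within 10% of the rate
  expect_lt(abs(mean(attr(h, "n_breakpoints")) - 3) / 3, 0.10)
  # and every placed breakpoint is visible as a label change
  line_changes <- rowSums(h[, 1:10] [, -1, drop = FALSE] != h[, 1:10][, -10, drop = FALSE])
  expect_true(all(line_changes <= attr(h, "n_breakpoints")[, 1]))
})

test_that("phenotypes are the planted genetic values plus environment noise", {
  cfg <- sim_config(n_lines = 40, n_chroms = 1, n_snps_per_chrom = 20,
                    breakpoint_rate = 2, seed = 7)
  h <- gen_founder_mosaic(cfg)
  q <- qtl_spec(10, c(0, 1, 2, 3, 4, 5, 6, 7))

  # noiseless limit: at most 8 distinct values, grouped exactly by haplotype
  ph <- gen_phenotypes(h, list(q), noise_sd = 0, n_environments = 2, seed = 8)
  y1 <- ph$value[ph$environment == "Y1"]
  expect_lte(length(unique(y1)), 8L)
  expect_equal(y1, q$effects[h[, 10]])
  # shared genetic part: environments identical without noise
  expect_equal(y1, ph$value[ph$environment == "Y2"])

  # pure-noise null model
  ph0 <- gen_phenotypes(h, list(), noise_sd = 2, n_environments = 1, seed = 9)
  expect_equal(sd(ph0$value), 2, tolerance = 0.35)
  expect_equal(mean(ph0$value), 0, tolerance = 1)

  expect_error(gen_phenotypes(h, list(q), noise_sd = -1), "non-negative")
  expect_error(gen_phenotypes(h, list(qtl_spec(999, rep(0, 8))), 1), "outside")
  expect_error(qtl_spec(1, 1:7), "8")
})

test_that("noise calibration yields the targeted fraction of explained variance", {
  cfg <- sim_config(seed = 10)
  h <- gen_founder_mosaic(cfg)
  q <- qtl_spec(500, c(-1.2, -0.8, -0.3, 0, 0.3, 0.8, 1.2, 1.6))
  nsd <- calibrate_noise_sd(h, q, 0.2)
  r2 <- vapply(1:10, function(s) {
    ph <- gen_phenotypes(h, list(q), nsd, n_environments = 1, seed = 100 + s)
    y <- ph$value
    g <- factor(h[, 500])
    summary(stats::lm(y ~ g))$r.squared
  }, numeric(1))
  expect_equal(mean(r2), 0.2, tolerance = 0.25)  # within ~5 points of 20%
})
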