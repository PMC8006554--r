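test_that("kruskal_wallis reproduces the worked example and textbook identities", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(res$H, 7.2)
  expect_identical(res$df, 2L)
  expect_equal(res$p, 0.0273, tolerance = 1e-3)
  expect_false(res$degenerate)

  # exchangeability: group order and within-group order are irrelevant
  res2 <- kruskal_wallis(list(c(9, 7, 8), c(3, 1, 2), c(6, 4, 5)))
  expect_equal(res2$H, res$H)
  expect_equal(res2$p, res$p)

  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(numeric(0), 1:3)), "at least one value")
  expect_error(kruskal_wallis(list(1, 2)), "at least 3")
  deg <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
})

test_that("kruskal_wallis agrees with stats::kruskal.test and the rank variance-ratio oracle under heavy ties", {
  set.seed(77)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j)
      sample(1:6, sample(3:10, 1), replace = TRUE) / 2)  # many ties
    x <- unlist(groups); g <- factor(rep.int(seq_len(k), lengths(groups)))
    ref <- suppressWarnings(stats::kruskal.test(x, g))
    res <- kruskal_wallis(groups)
    expect_equal(res$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    expect_equal(res$H, oracle_kw(groups), tolerance = 1e-12)
  }
})

test_that("the tie-corrected statistic equals the variance-ratio form over every exhaustive permutation at small N", {
  vals <- c(1, 1, 2, 3, 3, 4, 5)       # N = 7 with ties
  sizes <- c(3, 2, 2)
  perms <- pracma::perms(seq_along(vals))
  idx_split <- split(seq_along(vals), rep.int(seq_along(sizes), sizes))
  for (r in seq_len(nrow(perms))) {
    v <- vals[perms[r, ]]
    groups <- lapply(idx_split, function(ix) v[ix])
    expect_equal(kruskal_wallis(groups)$H, oracle_kw(groups), tolerance = 1e-12)
  }
})

test_that("group_compare matches the pooled t-test and its degenerate contracts", {
  res <- group_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_identical(res$df, 4L)
  expect_equal(res$p, 0.0213, tolerance = 1e-2)
  expect_identical(res$tier, "*")

  swapped <- group_compare(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)

  set.seed(14)
  a <- rnorm(12); b <- rnorm(9, 0.5)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  mine <- group_compare(a, b)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  same <- group_compare(c(2, 2, 2), c(2, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  degen <- group_compare(c(2, 2), c(3, 3))
  expect_true(degen$degenerate)
  expect_error(group_compare(1, c(2, 3)), "at least two")
})

test_that("run_gwas applies the few-haplotype discard rule and is permutation invariant", {
  cfg <- sim_config(n_lines = 60, n_chroms = 2, n_snps_per_chrom = 30,
                    breakpoint_rate = 2, seed = 21)
  map <- make_snp_map(2, 30)
  h <- gen_founder_mosaic(cfg, map)
  h[, 3] <- 1L                      # monomorphic SNP: one haplotype only
  h[, 4] <- rep(c(1L, 2L), 30)      # two haplotypes only
  q <- qtl_spec(45, c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5))
  ph <- gen_phenotypes(h, list(q), noise_sd = 0.5, seed = 22)

  g <- run_gwas(h, map, ph, "SDW", "Y1")
  expect_s3_class(g, "gwas_result")
  expect_equal(nrow(g), 60L)
  expect_identical(g$status[3], "discarded")
  expect_identical(g$status[4], "discarded")
  expect_true(all(is.na(g$p[g$status == "discarded"])))
  expect_true(all(g$neglog10p[g$status == "tested"] >= 0))
  expect_true(all(g$df[g$status == "tested"] == g$n_groups[g$status == "tested"] - 1L))

  # noiseless construction: causal SNP tops its chromosome
  ph0 <- gen_phenotypes(h, list(q), noise_sd = 0, seed = 23)
  g0 <- run_gwas(h, map, ph0, "SDW", "Y1")
  on_chr2 <- which(map$chrom == 2)
  expect_equal(which.max(g0$neglog10p[on_chr2]), match(45, on_chr2))

  # permuting line order of both inputs together changes nothing
  perm <- sample(nrow(h))
  g2 <- run_gwas(h[perm, ], map, ph[sample(nrow(ph)), ], "SDW", "Y1")
  expect_equal(g2$p, g$p)

  expect_error(run_gwas(h, map, ph, "LSA", "Y1"), "no phenotype values")
})

test_that("find_peaks reproduces the worked examples and the exhaustive oracle", {
  # spec examples (1-based indices here): [1,3,1,2,1]
  p1 <- find_peaks(c(1, 3, 1, 2, 1), min_distance = 1, n_top = 8)
  expect_equal(p1$index, c(2L, 4L))
  expect_equal(p1$height, c(3, 2))
  p2 <- find_peaks(c(1, 3, 1, 2, 1), min_distance = 3, n_top = 8)
  expect_equal(p2$index, 2L)

  expect_equal(nrow(find_peaks(1:50, 1, 8)), 0L)         # monotone: no peak
  expect_equal(nrow(find_peaks(c(2, 1), 1, 8)), 0L)      # too short
  expect_equal(find_peaks(c(1, 3, 3, 3, 1), 1, 8)$index, 2L)  # plateau: leftmost
  expect_equal(find_peaks(c(1, NA, 5, 2, 1), 1, 8)$index, 3L) # NA cannot be a peak

  set.seed(31)
  for (i in 1:20) {
    x <- round(rnorm(300), sample(0:2, 1))   # rounded -> plateaus and ties
    md <- sample(c(1, 5, 20, 100), 1)
    nt <- sample(c(3, 8, 50), 1)
    mine <- find_peaks(x, md, nt)
    ref <- oracle_find_peaks(x, md, nt)
    expect_equal(mine$index, ref$index)
    expect_equal(mine$height, ref$height)
    # spacing invariant
    if (nrow(mine) > 1)
      expect_true(min(dist(mine$index)) >= md)
  }
})

test_that("find_peaks candidates and min-distance selection match pracma's findpeaks on tie-free tracks", {
  skip_if_not_installed("pracma")
  set.seed(4)
  z <- rnorm(200)
  mine <- sort(find_peaks(z, 1, 1000)$index)
  ref <- sort(pracma::findpeaks(z)[, 2])
  expect_equal(as.integer(mine), as.integer(ref))
  mine15 <- sort(find_peaks(z, 15, 1000)$index)
  ref15 <- sort(pracma::findpeaks(z, minpeakdistance = 15, sortstr = TRUE)[, 2])
  expect_equal(as.integer(mine15), as.integer(ref15))
})

test_that("haplotype_effects recovers planted effects and applies the discard rule", {
  cfg <- sim_config(n_lines = 120, n_chroms = 1, n_snps_per_chrom = 10,
                    breakpoint_rate = 1, seed = 41)
  map <- make_snp_map(1, 10)
  h <- gen_founder_mosaic(cfg, map)
  effects <- c(0.5, -0.3, 1.2, 0, 2, -1, 0.7, 0.1)
  q <- qtl_spec(5, effects)
  ph <- gen_phenotypes(h, list(q), noise_sd = 0, seed = 42, baseline = 3)

  ev <- haplotype_effects(h, map, ph, "SDW", "Y1", map$snp_id[5])
  present <- !is.na(ev)
  # recovered up to the common additive baseline
  expect_equal(unname(ev[present]) - 3, effects[present], tolerance = 1e-12)
  expect_identical(names(ev), magic_founders)

  # founder absent at that SNP -> NA entry, rest defined
  h2 <- h; h2[h2[, 5] == 8L, 5] <- 1L
  ev2 <- haplotype_effects(h2, map, ph, "SDW", "Y1", map$snp_id[5])
  expect_true(is.na(ev2["RU"]))
  expect_equal(sum(!is.na(ev2)), sum(tabulate(h2[, 5], 8) > 0))

  # 2 haplotypes -> whole vector discarded
  h3 <- h; h3[, 5] <- rep(c(1L, 2L), 60)
  ev3 <- haplotype_effects(h3, map, ph, "SDW", "Y1", map$snp_id[5])
  expect_true(all(is.na(ev3)))
  expect_true(attr(ev3, "discarded"))

  expect_error(haplotype_effects(h, map, ph, "SDW", "Y1", "nope"), "unknown snp_id")
})

test_that("effect_correlation matches a direct covariance oracle and flags short vectors", {
  x <- as.numeric(1:8)
  expect_equal(effect_correlation(x, x)$r, 1)
  expect_equal(effect_correlation(x, -x)$r, -1)

  y <- c(2, 1, 4, 3, 6, 5, 8, 7)
  res <- effect_correlation(x, y)
  r_direct <- (mean(x * y) - mean(x) * mean(y)) /
    sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  ct <- stats::cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  expect_identical(res$n_used, 8L)

  # pairwise-complete behaviour and the <3 flag
  x2 <- c(1, 2, 3, NA, 5, NA, 7, 8)
  y2 <- c(2, NA, 4, 4, 6, 6, 8, 9)
  res2 <- effect_correlation(x2, y2)
  expect_identical(res2$n_used, 5L)
  expect_false(res2$flagged)
  expect_true(effect_correlation(c(1, 2, rep(NA, 6)), c(1, 2, rep(NA, 6)))$flagged)
  expect_true(effect_correlation(rep(1, 8), as.numeric(1:8))$flagged)
})
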