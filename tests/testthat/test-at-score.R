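test_that("merge_tiles is the pixel-wise mean with the expected algebra", {
  t1 <- matrix(1L, 9, 9)
  t0 <- matrix(0L, 9, 9)
  tiles <- c(list(t1), rep(list(t0), 8))
  m <- merge_tiles(tiles)
  expect_true(all(abs(m - 1 / 9) < 1e-12))

  # idempotence and permutation invariance
  set.seed(8)
  tb <- replicate(9, matrix(rbinom(81, 1, 0.5), 9, 9), simplify = FALSE)
  expect_equal(merge_tiles(rep(list(tb[[1]]), 9)), tb[[1]] * 1.0)
  expect_equal(merge_tiles(tb), merge_tiles(rev(tb)))

  expect_error(merge_tiles(tb[1:8]), "nine tiles")
  expect_error(merge_tiles(c(tb[1:8], list(matrix(0, 7, 7)))), "mismatched")
  expect_error(merge_tiles(rep(list(matrix(0, 8, 8)), 9)), "odd")
})

test_that("square-annuli regions partition the raster; areas match pixel enumeration", {
  r <- define_regions(9L, "square-annuli")
  expect_equal(sum(r$areas), 81L)
  expect_identical(r$weights, c(a = 1, b = 2, c = 3, d = 4, e = 5))
  # independent enumeration: ring of max-norm radius d has 8d pixels (d>0)
  expect_identical(unname(r$areas), c(32L, 24L, 16L, 8L, 1L))
  # centre pixel is innermost region
  expect_identical(r$labels[5, 5], "e")
  # rotation symmetry of the label matrix
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  expect_identical(rot90(r$labels), r$labels)

  r2 <- define_regions(45L)
  expect_equal(sum(r2$areas), 45L^2)
  expect_identical(rot90(r2$labels), r2$labels)
})

test_that("circular-annuli regions exclude corners beyond the outer circle", {
  r <- define_regions(21L, "circular-annuli")
  expect_true(any(is.na(r$labels)))            # corners excluded
  expect_true(is.na(r$labels[1, 1]))
  expect_identical(r$labels[11, 11], "e")
  expect_equal(sum(r$areas) + sum(is.na(r$labels)), 21L^2)
})

test_that("too-small sides for five non-empty regions are errors", {
  expect_error(define_regions(5L, "square-annuli"), "too small")
  expect_error(define_regions(7L, "square-annuli"), "too small")
  expect_silent(define_regions(9L, "square-annuli"))
  expect_error(define_regions(4L), "odd")
})

test_that("AT is 15 for uniform masks and 25/5 for mass innermost/outermost on equal-area geometry", {
  reg <- define_regions(45L)
  u <- matrix(0.37, 45, 45)
  expect_equal(compute_at(u, reg)$at, 15)

  ea <- equal_area_regions()
  inner <- matrix(0, 15, 15); inner[ea$labels == "e"] <- 0.8
  outer <- matrix(0, 15, 15); outer[ea$labels == "a"] <- 0.8
  expect_equal(compute_at(inner, ea)$at, 25)
  expect_equal(compute_at(outer, ea)$at, 5)
})

test_that("AT is scale invariant and increases when mass moves inward", {
  set.seed(12)
  ea <- equal_area_regions()
  m <- matrix(runif(225), 15, 15)
  at1 <- compute_at(m, ea)$at
  for (c in c(0.01, 3, 250)) expect_equal(compute_at(c * m, ea)$at, at1)

  # moving mass from an outer to an inner region strictly increases AT
  # whenever weight_inner/area_inner > weight_outer/area_outer (equal areas)
  m2 <- m
  i_a <- which(ea$labels == "a" & m > 0.2)[1]
  i_d <- which(ea$labels == "d")[1]
  m2[i_a] <- m2[i_a] - 0.2
  m2[i_d] <- m2[i_d] + 0.2
  expect_gt(compute_at(m2, ea)$at, at1)

  expect_error(compute_at(matrix(0, 15, 15), ea), "no plant signal")
  expect_error(compute_at(matrix(1, 7, 7), ea), "match")
})

test_that("AT decreases with the spreading-habit parameter end to end", {
  lay <- layout_small()
  spreads <- c(0.1, 0.5, 0.9)
  ats <- vapply(spreads, function(sp) {
    mean(vapply(1:4, function(sd) {
      sc <- gen_canopy_scene(lay, 0.3, sp, seed = sd)
      measure_at(segment_plants(rgb_to_astar(sc$image)), lay)$at
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ats) < 0))
})
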