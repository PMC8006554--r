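test_that("a* conversion hits the classical reference values", {
  expect_equal(rgb_to_astar(matrix(c(128, 128, 128), 1)), 0, tolerance = 1e-6)
  expect_equal(rgb_to_astar(matrix(c(0, 0, 0), 1)), 0, tolerance = 1e-6)
  expect_equal(rgb_to_astar(matrix(c(255, 255, 255), 1)), 0, tolerance = 1e-6)
  expect_equal(rgb_to_astar(matrix(c(0, 255, 0), 1)), -86.18, tolerance = 0.01)
  expect_equal(rgb_to_astar(matrix(c(255, 0, 0), 1)), 80.11, tolerance = 0.001)
  # array input returns a matrix of matching size
  img <- array(sample(0:255, 60, TRUE), c(4, 5, 3))
  a <- rgb_to_astar(img)
  expect_equal(dim(a), c(4L, 5L))
  expect_error(rgb_to_astar(array(0, c(4, 5, 2))), "8-bit sRGB")
  expect_error(rgb_to_astar(matrix(300, 1, 3)), "0..255")
})

test_that("otsu_threshold resolves the worked tie and degenerate cases", {
  h <- integer(256); h[11] <- 50; h[201] <- 50
  expect_identical(otsu_threshold(h), 104L)   # plateau [10,199], midpoint
  h2 <- integer(256); h2[101] <- 50; h2[102] <- 50
  expect_identical(otsu_threshold(h2), 100L)
  h3 <- integer(256); h3[8] <- 99
  expect_error(otsu_threshold(h3), "single occupied bin")
  expect_error(otsu_threshold(integer(256)), "empty")
  expect_error(otsu_threshold(integer(100)), "256-bin")
})

test_that("otsu_threshold matches the exhaustive-search oracle exactly, and maximizing between-class variance equals minimizing within-class variance", {
  set.seed(421)
  for (i in 1:120) {
    h <- random_histogram()
    o <- oracle_otsu(h)
    expect_identical(otsu_threshold(h), o$threshold)
    expect_identical(o$optimal_set, o$optimal_set_within)
  }
})

test_that("segmentation keeps the plant class on the low-a* side", {
  # half pure green / half pure red -> VF exactly 50
  img <- array(0L, c(10, 10, 3))
  img[, 1:5, 2] <- 255L   # green half
  img[, 6:10, 1] <- 255L  # red half
  m <- segment_plants(rgb_to_astar(img))
  expect_equal(compute_vf(m), 50)
  expect_true(all(m$values[, 1:5] == 1L))

  # polarity does not flip when the green class is the majority or minority
  img2 <- array(0L, c(10, 10, 3)); img2[, 1:8, 2] <- 255L; img2[, 9:10, 1] <- 255L
  img3 <- array(0L, c(10, 10, 3)); img3[, 1:2, 2] <- 255L; img3[, 3:10, 1] <- 255L
  expect_equal(compute_vf(segment_plants(rgb_to_astar(img2))), 80)
  expect_equal(compute_vf(segment_plants(rgb_to_astar(img3))), 20)

  # explicit inversion flag flips it
  expect_equal(compute_vf(segment_plants(rgb_to_astar(img3), polarity = "high")), 80)
  expect_error(segment_plants(matrix(1.5, 4, 4)), "constant")
})

test_that("segmentation recovers generator ground truth on a synthetic scene", {
  sc <- gen_canopy_scene(plot_layout(), 0.5, 0.5, seed = 1)
  m <- segment_plants(rgb_to_astar(sc$image))
  agreement <- mean((m$values == 1L) == (sc$truth_mask == 1L))
  expect_gte(agreement, 0.95)
})

test_that("compute_vf is the plant-pixel percentage with strict monotonicity", {
  mask <- matrix(0L, 270, 450)
  mask[seq_len(60750)] <- 1L
  expect_equal(compute_vf(mask), 50)
  expect_equal(compute_vf(matrix(0L, 5, 5)), 0)
  expect_equal(compute_vf(matrix(1L, 5, 5)), 100)
  expect_error(compute_vf(matrix(integer(0), 0, 0)), "empty")
  # flipping any single background pixel strictly increases VF
  set.seed(5)
  m <- matrix(rbinom(100, 1, 0.4), 10, 10)
  zeros <- which(m == 0L)
  for (i in sample(zeros, 5)) {
    m2 <- m; m2[i] <- 1L
    expect_gt(compute_vf(m2), compute_vf(m))
  }
})
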