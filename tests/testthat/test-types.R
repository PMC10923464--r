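test_that("mask measure is exactly occupied count times voxel measure", {
  g <- matrix(FALSE, 20, 30)
  g[3:12, 5:24] <- TRUE
  m <- cell_mask(g, c(x = 50, y = 40))
  expect_identical(m$measure, sum(g) * 50 * 40)

  g3 <- array(runif(8 * 6 * 4) > 0.5, c(8, 6, 4))
  g3[1, 1, 1] <- TRUE
  m3 <- cell_mask(g3, c(x = 100, y = 100, z = 200))
  expect_identical(m3$measure, sum(g3) * 100 * 100 * 200)
  expect_error(cell_mask(array(FALSE, c(4, 4)), 100), "empty")
})

test_that("spot_set validates coordinates and dimensions", {
  s <- spot_set(cbind(x = c(0, 10), y = c(5, 5)))
  expect_equal(s$n, 2)
  expect_equal(s$dim, 2)
  expect_error(spot_set(cbind(x = c(0, NA), y = c(1, 2))), "finite")
  expect_error(spot_set(matrix(1, 2, 4)), "2 or 3 columns")
})

test_that("ring_spec enforces the increasing-from-zero contract", {
  r <- ring_spec(c(0, 30, 60))
  expect_equal(r$K, 2)
  expect_error(ring_spec(c(10, 20)), "r_0 = 0")
  expect_error(ring_spec(c(0, 30, 30)), "increasing")
})

test_that("nm/grid conversion follows the pixel-corner convention", {
  ps <- c(x = 100, y = 100)
  # centre of 0-based pixel (row 0, col 3) is x = 350, y = 50
  idx <- sodamap:::nm_to_index(cbind(x = 350, y = 50), ps)
  expect_equal(unname(idx), matrix(c(1L, 4L), 1))
  pos <- sodamap:::index_to_nm(matrix(c(1, 4), 1), ps)
  expect_equal(unname(pos), matrix(c(350, 50), 1))
})

test_that("uniform mask samples stay inside the mask", {
  g <- matrix(FALSE, 30, 30)
  g[10:20, 5:25] <- TRUE
  m <- cell_mask(g, 100)
  set.seed(1)
  p <- sodamap:::sample_in_mask(m, 500)
  expect_true(all(sodamap:::mask_contains(m, p)))
})
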