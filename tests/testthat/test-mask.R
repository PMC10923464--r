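test_that("a two-valued image yields one exactly partitioning threshold", {
  set.seed(5)
  img <- matrix(c(10, 200)[1 + (runif(400) > 0.6)], 20, 20)
  th <- kmeans_intensity_thresholds(img, K = 2)
  expect_length(th, 1)
  expect_gt(th, 10)
  expect_lt(th, 200)
  expect_identical(img > th, img == 200)
})

test_that("degenerate histograms are rejected", {
  expect_error(kmeans_intensity_thresholds(matrix(5, 10, 10), K = 2),
               "degenerate histogram")
  expect_error(kmeans_intensity_thresholds(matrix(c(1, 2), 4, 4), K = 3),
               "degenerate histogram")
})

test_that("bimodal mixture threshold matches the exhaustive oracle", {
  set.seed(7)
  v <- c(rnorm(32768, 50, 5), rnorm(32768, 180, 5))
  img <- matrix(pmax(v, 0), 256, 256)
  th <- kmeans_intensity_thresholds(img, K = 2)
  expect_gt(th, 80)
  expect_lt(th, 150)
  expect_equal(th, oracle_otsu_like(img), tolerance = 2 / th)
})

test_that("a bright disk is segmented with IoU >= 0.95", {
  ny <- nx <- 100
  truth <- outer(seq_len(ny) - 50.5, seq_len(nx) - 50.5,
                 function(a, b) a^2 + b^2 <= 20^2)
  img <- ifelse(truth, 200, 10) + matrix(rnorm(ny * nx, 0, 3), ny, nx)
  m <- segment_cell_mask(img, hk_params(n_classes = 2,
                                        foreground_classes = 1), 100)
  iou <- sum(m$grid & truth) / sum(m$grid | truth)
  expect_gte(iou, 0.95)
  expect_identical(m$measure, sum(m$grid) * 100 * 100)
})

test_that("small bright specks are removed by the size filter", {
  ny <- nx <- 100
  disk <- outer(seq_len(ny) - 50.5, seq_len(nx) - 50.5,
                function(a, b) a^2 + b^2 <= 20^2)
  img <- ifelse(disk, 200, 10)
  for (corner in list(c(5, 5), c(5, 90), c(90, 8))) {
    img[corner[1] + 0:1, corner[2] + 0:1] <- 200 # 4-px specks
  }
  m <- segment_cell_mask(img, hk_params(n_classes = 2,
                                        foreground_classes = 1,
                                        min_size_px = 50,
                                        dilation_px = 0), 100)
  expect_false(any(m$grid[1:10, 1:10]))
  expect_false(any(m$grid[1:10, 85:100]))
  expect_true(any(m$grid[45:55, 45:55]))
})

test_that("an all-background image reports no cell", {
  img <- matrix(10, 50, 50) + matrix(runif(2500), 50, 50)
  expect_error(segment_cell_mask(img, hk_params(min_size_px = 1e5)),
               "no cell")
})

test_that("the mask is invariant to affine intensity rescaling", {
  set.seed(12)
  ny <- nx <- 80
  disk <- outer(seq_len(ny) - 40.5, seq_len(nx) - 40.5,
                function(a, b) a^2 + b^2 <= 18^2)
  img <- ifelse(disk, 180, 12) + matrix(rnorm(ny * nx, 0, 4), ny, nx)
  m1 <- segment_cell_mask(img, hk_params(n_classes = 2,
                                         foreground_classes = 1), 100)
  m2 <- segment_cell_mask(3.5 * img + 40,
                          hk_params(n_classes = 2, foreground_classes = 1),
                          100)
  expect_identical(m1$grid, m2$grid)
})

test_that("the K-sweep picks the smallest K with an in-bounds component", {
  ny <- nx <- 80
  disk <- outer(seq_len(ny) - 40.5, seq_len(nx) - 40.5,
                function(a, b) a^2 + b^2 <= 18^2)
  img <- ifelse(disk, 180, 12)
  m <- segment_cell_mask(img, hk_params(n_classes = 2,
                                        foreground_classes = 1,
                                        min_size_px = 100,
                                        max_size_px = 5000),
                         100, sweep_k = 2:4)
  expect_gt(sum(m$grid), 900)
})
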