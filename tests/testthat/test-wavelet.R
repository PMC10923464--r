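test_that("wavelet planes of a constant image vanish and telescope", {
  img <- matrix(7, 32, 32)
  w <- atrous_wavelet(img, S = 3)
  for (p in w$planes) expect_lt(max(abs(p)), 1e-12)
  noisy <- matrix(rpois(48 * 40, 20), 48, 40)
  w2 <- atrous_wavelet(noisy, S = 4)
  rec <- Reduce(`+`, w2$planes) + w2$residual
  expect_lt(max(abs(rec - noisy)) / max(noisy), 1e-6)
  vol <- array(runif(16 * 16 * 8), c(16, 16, 8))
  w3 <- atrous_wavelet(vol, S = 2)
  rec3 <- Reduce(`+`, w3$planes) + w3$residual
  expect_lt(max(abs(rec3 - vol)) / max(vol), 1e-6)
})

test_that("scale-2 detail peaks at the centre of a sigma=2 Gaussian", {
  img <- gaussian_spot_image(64, 64, cbind(32, 32), sigma = 2)
  w <- atrous_wavelet(img, S = 2)
  peak <- arrayInd(which.max(w$planes[[2]]), dim(img))
  expect_equal(as.vector(peak), c(32, 32), tolerance = 1)
})

test_that("oversized scale counts are rejected", {
  expect_error(atrous_wavelet(matrix(0, 8, 8), S = 6), "S too large")
})

test_that("detection handles empty and single-spot images", {
  expect_equal(detect_spots(matrix(0, 32, 32))$n, 0)
  img <- gaussian_spot_image(64, 64, cbind(32, 32), sigma = 2,
                             amplitude = 100)
  s <- detect_spots(img, detection_params(), pixel_size = 100)
  expect_equal(s$n, 1)
  # centroid within 0.5 px of the true centre (100 nm pixels)
  expect_lt(sqrt(sum((s$positions[1, ] - c(3200, 3200))^2)), 50)
})

test_that("two noisy spots 20 px apart are both recovered", {
  set.seed(11)
  img <- gaussian_spot_image(64, 64, rbind(c(22, 32), c(42, 32)),
                             sigma = 2, amplitude = 100) +
    matrix(rpois(64 * 64, 2), 64, 64)
  # the scale-1 conjunction suppresses single-scale noise blobs
  s <- detect_spots(img, detection_params(scales = c(1, 2), k_sigma = 3),
                    pixel_size = 100)
  expect_equal(s$n, 2)
  truth <- rbind(c(2200, 3200), c(4200, 3200))
  m <- match_detections(truth, s$positions, radius = 100)
  expect_equal(unname(m["recall"]), 1)
})

test_that("detection is translation-equivariant for interior spots", {
  set.seed(3)
  big <- gaussian_spot_image(80, 90, rbind(c(35, 25), c(60, 50)),
                             sigma = 2, amplitude = 80) +
    matrix(rpois(80 * 90, 1), 80, 90)
  img <- big[, 1:80]      # spots at x = 35, 60
  shifted <- big[, 6:85]  # same content shifted by -5 px in x
  s0 <- detect_spots(img, detection_params(k_sigma = 4), pixel_size = 100)
  s1 <- detect_spots(shifted, detection_params(k_sigma = 4),
                     pixel_size = 100)
  expect_equal(s1$n, s0$n)
  ord0 <- order(s0$positions[, "x"])
  ord1 <- order(s1$positions[, "x"])
  expect_equal(unname(s1$positions[ord1, "x"]),
               unname(s0$positions[ord0, "x"]) - 500, tolerance = 0.01)
  expect_equal(unname(s1$positions[ord1, "y"]),
               unname(s0$positions[ord0, "y"]), tolerance = 0.01)
})

test_that("raising k_sigma never increases the spot count", {
  set.seed(21)
  sc <- sim_scenario(mask_shape = "disk", N1 = 30, N2 = 0,
                     coupled_fraction = 0, nx = 150, ny = 150,
                     min_separation = 600, seed = 21)
  pat <- simulate_patterns(sc)
  img <- render_image(pat$mask, pat$spots1, pat$spots2, sc)
  ch <- get_channel(img, 1)
  n3 <- detect_spots(ch, detection_params(k_sigma = 3), 100)$n
  n4 <- detect_spots(ch, detection_params(k_sigma = 4), 100)$n
  expect_lte(n4, n3)
  expect_gt(n3, 0)
})
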