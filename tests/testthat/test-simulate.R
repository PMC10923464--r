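test_that("patterns respect counts, masks, and determinism", {
  sc <- sim_scenario(N1 = 100, N2 = 80, coupled_fraction = 0.4, seed = 14)
  pat <- simulate_patterns(sc)
  expect_equal(pat$spots1$n, 100)
  expect_equal(pat$spots2$n, 80)
  expect_true(all(sodamap:::mask_contains(pat$mask, pat$spots1$positions)))
  expect_true(all(sodamap:::mask_contains(pat$mask, pat$spots2$positions)))
  expect_equal(sum(!is.na(pat$truth$partner)), round(0.4 * 80))
  pat2 <- simulate_patterns(sc)
  expect_identical(pat$spots2$positions, pat2$spots2$positions)
})

test_that("q=1 with zero jitter places every point at exactly d_c", {
  sc <- sim_scenario(N1 = 50, N2 = 50, coupled_fraction = 1,
                     coupling_distance = 70, jitter_sd = 0, seed = 15)
  pat <- simulate_patterns(sc)
  d <- sqrt(rowSums((pat$spots2$positions -
                       pat$spots1$positions[pat$truth$partner, ])^2))
  expect_equal(d, rep(70, 50), tolerance = 1e-9)
})

test_that("coupling with no channel-1 points is rejected", {
  expect_error(simulate_patterns(sim_scenario(N1 = 0, N2 = 10,
                                              coupled_fraction = 0.5)),
               "N1 = 0")
})

test_that("realised partner distances follow the folded-normal law", {
  sc <- sim_scenario(N1 = 200, N2 = 400, coupled_fraction = 1,
                     coupling_distance = 50, jitter_sd = 10, seed = 16)
  pat <- simulate_patterns(sc)
  d <- sqrt(rowSums((pat$spots2$positions -
                       pat$spots1$positions[pat$truth$partner, ])^2))
  # E|N(50, 10^2)| with mu/sigma = 5 is mu to excellent approximation
  expect_lt(abs(mean(d) - 50), 3 * 10 / sqrt(400))
})

test_that("neurite masks are thin connected processes", {
  sc <- sim_scenario(mask_shape = "neurite", nx = 200, ny = 200,
                     N1 = 50, N2 = 50, seed = 17)
  pat <- simulate_patterns(sc)
  expect_gt(sum(pat$mask$grid), 0)
  expect_lt(mean(pat$mask$grid), 0.5) # thin: covers a minority of the field
  expect_true(all(sodamap:::mask_contains(pat$mask, pat$spots1$positions)))
})

test_that("rendering places photons where the spots are", {
  m <- cell_mask(matrix(TRUE, 64, 64), 100)
  sc <- sim_scenario(nx = 64, ny = 64, psf_sigma_px = 2,
                     photon_scale = 5000, background_rate = 0, seed = 18)
  s1 <- spot_set(cbind(x = 3250, y = 1850))
  s0 <- spot_set(matrix(numeric(0), 0, 2))
  img <- render_image(m, s1, s0, sc)
  ch <- get_channel(img, 1)
  peak <- arrayInd(which.max(ch), dim(ch))
  expect_equal(as.vector(peak), c(19, 33), tolerance = 1) # row y, col x

  sc0 <- sim_scenario(nx = 64, ny = 64, photon_scale = 0,
                      background_rate = 3, seed = 19)
  img0 <- render_image(m, s1, s0, sc0)
  ch0 <- get_channel(img0, 1)
  expect_lt(abs(mean(ch0) - 3), 0.3) # pure background
})

test_that("simulate_batch writes a reproducible fixture folder", {
  dir1 <- withr_tempdir()
  dir2 <- withr_tempdir()
  scs <- lapply(1:3, function(k)
    sim_scenario(N1 = 20, N2 = 20, nx = 48, ny = 48,
                 coupled_fraction = 0.5, seed = k))
  man1 <- simulate_batch(scs, dir1)
  expect_equal(nrow(man1), 3)
  expect_true(all(file.exists(file.path(dir1, man1$ch1))))
  expect_true(all(file.exists(file.path(dir1, man1$image))))
  man2 <- simulate_batch(scs, dir2)
  for (f in c(man1$ch1, man1$ch2, man1$truth))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  empty <- simulate_batch(list(), withr_tempdir())
  expect_equal(nrow(empty), 0)
})
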