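full_mask <- function(n = 100, ps = 100) cell_mask(matrix(TRUE, n, n), ps)

test_that("pair binning is half-open with boundary ties to the outer ring", {
  s1 <- spot_set(cbind(x = 0.5, y = 0.5))
  s2 <- spot_set(cbind(x = 5.5, y = 0.5))
  p <- pair_distances(s1, s2, ring_spec(c(0, 10)))
  expect_equal(nrow(p), 1)
  expect_equal(p$d, 5)
  expect_equal(p$ring, 1)

  s3 <- spot_set(cbind(x = 10.5, y = 0.5)) # d exactly = r_1 = 10
  p2 <- pair_distances(s1, s3, ring_spec(c(0, 10, 20)))
  expect_equal(p2$ring, 2)

  s4 <- spot_set(cbind(x = c(1, 2), y = c(1, 2), z = c(1, 2)))
  expect_error(pair_distances(s1, s4, ring_spec(c(0, 10))),
               "dimension mismatch")
})

test_that("indexed pair search equals the brute-force double loop", {
  set.seed(31)
  m <- full_mask(100, 100) # 10 um box
  s1 <- spot_set(sodamap:::sample_in_mask(m, 200))
  s2 <- spot_set(sodamap:::sample_in_mask(m, 200))
  got <- pair_distances(s1, s2, ring_spec(seq(0, 500, 100)))
  got <- got[order(got$i, got$j), ]
  want <- oracle_pairs(s1, s2, 500)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$i, want$i)
  expect_equal(got$j, want$j)
  expect_equal(got$d, want$d, tolerance = 1e-12)
})

test_that("edge weights reproduce the symmetry-forced geometries", {
  m <- full_mask(200, 50) # 10 um box at 50 nm pixels
  centre <- c(5000, 5000)
  expect_equal(edge_weight(centre, 1000, m), 1)

  half <- cell_mask(cbind(matrix(TRUE, 200, 100), matrix(FALSE, 200, 100)),
                    50)
  p_edge <- c(5000 - 1e-6, 5000)
  expect_equal(edge_weight(p_edge, 1000, half), 2, tolerance = 0.01)

  quarter <- matrix(FALSE, 200, 200)
  quarter[1:100, 1:100] <- TRUE
  qm <- cell_mask(quarter, 50)
  p_corner <- c(5000 - 1e-6, 5000 - 1e-6)
  expect_equal(edge_weight(p_corner, 1000, qm), 4, tolerance = 0.0125)

  expect_error(edge_weight(c(9000, 5000), 100, half), "outside mask")
})

test_that("edge weights are capped at 20 for engulfing radii", {
  m <- full_mask(20, 50) # 1 um box
  w <- edge_weight(c(500, 500), 50000, m)
  expect_equal(w, 20)
})

test_that("the single-pair profile matches the definition arithmetic", {
  # |Omega| = 100x100 px * (10 nm)^2 = 1e6 nm^2; one interior pair at d=5
  m <- full_mask(100, 10)
  s1 <- spot_set(cbind(x = 500, y = 500))
  s2 <- spot_set(cbind(x = 505, y = 500))
  pr <- ripley_profile(s1, s2, ring_spec(c(0, 10)), m)
  expect_equal(pr$K_hat, 1e6)
  expect_equal(pr$A, pi * 100, tolerance = 1e-12)

  far <- spot_set(cbind(x = 900, y = 500))
  pr0 <- ripley_profile(s1, far, ring_spec(c(0, 10, 20)), m)
  expect_equal(pr0$K_hat, c(0, 0))
})

test_that("indexed K-hat equals the brute-force oracle on seeded cases", {
  rings <- ring_spec(seq(0, 200, 50))
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    m <- if (seed %% 2) full_mask(60, 100) else
      cell_mask(outer(1:60, 1:60, function(a, b)
        (a - 30)^2 + (b - 30)^2 <= 28^2), 100)
    s1 <- spot_set(sodamap:::sample_in_mask(m, 50))
    s2 <- spot_set(sodamap:::sample_in_mask(m, 50))
    pr <- ripley_profile(s1, s2, rings, m)
    expect_equal(pr$K_hat, oracle_khat(s1, s2, rings, m),
                 tolerance = 1e-9)
  }
})

test_that("3D profiles use shell volumes and 3D weights", {
  g <- array(TRUE, c(20, 20, 10))
  m <- cell_mask(g, c(x = 100, y = 100, z = 100))
  rings <- ring_spec(c(0, 150, 300))
  expect_equal(ripley_profile(spot_set(cbind(x = 1000, y = 1000, z = 500)),
                              spot_set(cbind(x = 1100, y = 1000, z = 500)),
                              rings, m)$A,
               (4 / 3) * pi * c(150^3, 300^3 - 150^3), tolerance = 1e-12)
  set.seed(41)
  s1 <- spot_set(sodamap:::sample_in_mask(m, 30))
  s2 <- spot_set(sodamap:::sample_in_mask(m, 30))
  pr <- ripley_profile(s1, s2, rings, m)
  expect_equal(pr$K_hat, oracle_khat(s1, s2, rings, m), tolerance = 1e-9)
})

test_that("Monte-Carlo null mean matches the ring measure under CSR", {
  m <- full_mask(100, 100)
  set.seed(51)
  s1 <- spot_set(sodamap:::sample_in_mask(m, 50))
  rings <- rings_uniform(300, 100)
  nm <- null_moments(s1, 50, rings, m, B = 800, seed = 9)
  se <- nm$sd / sqrt(nm$B)
  A <- sodamap:::ring_measure(rings, 2)
  expect_true(all(abs(nm$mean - A) < 3 * se))
  # deterministic given seed
  nm2 <- null_moments(s1, 50, rings, m, B = 800, seed = 9)
  expect_identical(nm$mean, nm2$mean)
})

test_that("null sd estimates agree across resample sizes", {
  m <- full_mask(80, 100)
  set.seed(52)
  s1 <- spot_set(sodamap:::sample_in_mask(m, 40))
  rings <- rings_uniform(300, 150)
  sd_small <- null_moments(s1, 40, rings, m, B = 150, seed = 1)$sd
  sd_big <- null_moments(s1, 40, rings, m, B = 1200, seed = 1)$sd
  expect_true(all(abs(sd_small - sd_big) / sd_big < 0.25))
})

test_that("extreme rings with one point keep the moments finite", {
  m <- full_mask(20, 50) # 1 um box, rings far beyond it
  set.seed(53)
  s1 <- spot_set(sodamap:::sample_in_mask(m, 5))
  nm <- null_moments(s1, 1, ring_spec(c(0, 5000, 10000)), m, B = 100,
                     seed = 2)
  expect_true(all(is.finite(nm$mean)))
  expect_true(all(is.finite(nm$sd)))
})

test_that("coupling probabilities follow the excess-ratio definition", {
  rings <- ring_spec(c(0, 50, 100))
  prof <- structure(list(
    K_hat = c(2 * pi * 50^2, pi * (100^2 - 50^2) * 0.5),
    A = sodamap:::ring_measure(rings, 2), rings = rings,
    pairs = data.frame(i = c(1, 2), j = c(1, 2), d = c(40, 60),
                       w = c(1, 1), ring = c(1, 2)),
    n1 = 10, n2 = 10, dim = 2), class = "ripley_profile")
  mom <- list(mean = prof$A, sd = c(1, 1), B = 100)
  cp <- coupling_probabilities(prof, mom, alpha = 0.05)
  expect_equal(cp$p_ring[1], 0.5) # K = 2A -> (2A-A)/2A
  expect_equal(cp$p_ring[2], 0)   # K <= A -> 0 regardless
  expect_equal(cp$n_coupled, 0.5)
  expect_equal(cp$mu_d, 40)
})

test_that("weighted distance moments average the retained pairs", {
  rings <- ring_spec(c(0, 100))
  A <- sodamap:::ring_measure(rings, 2)
  prof <- structure(list(
    K_hat = 2 * A, A = A, rings = rings,
    pairs = data.frame(i = c(1, 2), j = c(1, 2), d = c(40, 60),
                       w = c(1, 1), ring = c(1, 1)),
    n1 = 5, n2 = 5, dim = 2), class = "ripley_profile")
  cp <- coupling_probabilities(prof, list(mean = A, sd = 1, B = 100),
                               alpha = 0.05)
  expect_equal(cp$mu_d, 50)
  expect_equal(cp$sd_d, 10)
  expect_equal(cp$coupling_fraction_ch1, cp$n_coupled / 5)
})

test_that("degenerate inputs yield no coupling and p-value near 1", {
  m <- full_mask(100, 100)
  s1 <- spot_set(cbind(x = 2000, y = 2000))
  s2 <- spot_set(cbind(x = 8000, y = 8000))
  res <- run_soda(s1, s2, m, rings_uniform(300, 100), B = 100, seed = 1)
  expect_equal(res$coupling$n_coupled, 0)
  expect_true(is.na(res$coupling$mu_d))
  expect_gt(res$coupling$p_value, 0.5)
})

test_that("identical patterns are maximally coupled", {
  m <- full_mask(100, 100)
  set.seed(61)
  s1 <- spot_set(sodamap:::sample_in_mask(m, 100))
  res <- run_soda(s1, s1, m, rings_uniform(300, 30), B = 300, seed = 3)
  expect_lt(res$coupling$p_value, 1e-6)
  expect_lt(res$coupling$mu_d, 30) # inside the first ring
  expect_gt(res$coupling$coupling_fraction_ch1, 0.9)
})

test_that("run_soda is deterministic given its seed", {
  pat <- simulate_patterns(sim_scenario(N1 = 60, N2 = 60,
                                        coupled_fraction = 0.4, seed = 8))
  r1 <- run_soda(pat$spots1, pat$spots2, pat$mask, rings_uniform(300, 30),
                 B = 150, seed = 99)
  r2 <- run_soda(pat$spots1, pat$spots2, pat$mask, rings_uniform(300, 30),
                 B = 150, seed = 99)
  expect_identical(r1$coupling$n_coupled, r2$coupling$n_coupled)
  expect_identical(r1$coupling$p_value, r2$coupling$p_value)
})
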