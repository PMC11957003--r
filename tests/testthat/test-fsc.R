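test_that("FSC of a map with itself is 1 and with its negation is -1", {
  m <- random_grid(n = 16L, seed = 41)
  self <- fsc_curve(m, m)
  expect_true(all(abs(self$correlation - 1) < 1e-9))
  expect_true(all(diff(self$shell_freq) > 0))
  neg <- m
  neg$data <- -m$data
  anti <- fsc_curve(m, neg)
  expect_true(all(abs(anti$correlation + 1) < 1e-9))
})

test_that("FSC is symmetric and invariant under positive scaling", {
  a <- random_grid(n = 12L, seed = 43)
  b <- random_grid(n = 12L, seed = 44)
  ab <- fsc_curve(a, b)
  ba <- fsc_curve(b, a)
  expect_equal(ab$correlation, ba$correlation, tolerance = 1e-12)
  a5 <- a
  a5$data <- 5 * a$data
  expect_equal(fsc_curve(a5, b)$correlation, ab$correlation,
               tolerance = 1e-12)
  expect_true(all(abs(ab$correlation) <= 1 + 1e-9))
})

test_that("the FFT path matches the direct-DFT oracle on 16^3 grids", {
  for (seed in c(51, 52)) {
    a <- random_grid(n = 16L, seed = seed)
    b <- a
    b$data <- a$data + 0.5 * random_grid(n = 16L, seed = seed + 100)$data
    prod_curve <- fsc_curve(a, b)
    oracle <- oracle_fsc(a, b)
    expect_equal(prod_curve$shell_freq, oracle$shell_freq, tolerance = 1e-12)
    expect_equal(prod_curve$correlation, oracle$correlation,
                 tolerance = 1e-6)
  }
  # and on an anisotropic box
  a <- voxel_grid(array(rnorm(12 * 10 * 8), dim = c(12, 10, 8)),
                  voxel_size = c(1, 1.25, 1.5))
  b <- voxel_grid(a$data + rnorm(length(a$data), sd = 0.3),
                  voxel_size = c(1, 1.25, 1.5))
  expect_equal(fsc_curve(a, b)$correlation, oracle_fsc(a, b)$correlation,
               tolerance = 1e-6)
})

test_that("independent white-noise maps decorrelate shell-wise", {
  a <- random_grid(n = 64L, seed = 61)
  b <- random_grid(n = 64L, seed = 62)
  cv <- fsc_curve(a, b)
  bound <- 3 / sqrt(cv$n_voxels)
  expect_gte(mean(abs(cv$correlation) <= bound), 0.95)
})

test_that("threshold crossing interpolates linearly between shells", {
  curve <- structure(
    data.frame(shell_freq = c(0.1, 0.2), correlation = c(0.8, 0.4),
               n_voxels = c(10L, 20L)),
    class = c("fsc_curve", "data.frame"), voxel_size = c(1, 1, 1))
  est <- resolution_at_threshold(curve, 0.5)
  expect_true(est$crossed)
  expect_equal(est$resolution, 1 / 0.175, tolerance = 1e-12)  # ~5.714 A

  # never crossed: Nyquist convention
  flat <- structure(
    data.frame(shell_freq = c(0.1, 0.2, 0.3), correlation = c(1, 1, 1),
               n_voxels = rep(5L, 3)),
    class = c("fsc_curve", "data.frame"), voxel_size = c(1, 1, 1))
  est2 <- resolution_at_threshold(flat, 0.143)
  expect_false(est2$crossed)
  expect_equal(est2$resolution, 2)

  # immediately below threshold: first shell frequency
  est3 <- resolution_at_threshold(curve, 0.9)
  expect_true(est3$crossed)
  expect_equal(est3$resolution, 1 / 0.1)
})

test_that("geometry mismatches and zero maps are rejected", {
  a <- random_grid(n = 8L, seed = 71)
  b <- random_grid(n = 10L, seed = 72)
  expect_error(fsc_curve(a, b), "alignment")
  z <- empty_grid(8L)
  expect_error(fsc_curve(a, z), "all-zero")
})

test_that("map-model FSC of a self-simulated map is 1 everywhere", {
  s <- make_helix(3)
  ref <- empty_grid(c(24L, 20L, 20L), voxel_size = 1, origin = c(-7, -7, -7))
  p <- simulation_params(3)
  sim <- simulate_on_map(s, ref, p)
  cv <- map_model_fsc(sim, s, p)
  expect_true(all(abs(cv$correlation - 1) < 1e-9))
})

test_that("misalignment degrades the map-model FSC resolution", {
  s <- make_helix(4)
  maps <- make_noisy_map(s, fixture_spec(n_residues = 4, noise_sigma = 0.01,
                                         seed = 5))
  p <- simulation_params(3)
  aligned <- resolution_at_threshold(map_model_fsc(maps$noisy, s, p), 0.5)
  shifted <- s
  shifted$x <- s$x + 10
  cv_shift <- map_model_fsc(maps$noisy, shifted, p)
  bad <- resolution_at_threshold(cv_shift, 0.5)
  expect_gt(bad$resolution, aligned$resolution)
})

test_that("increasing noise never improves the FSC 0.143 resolution", {
  s <- make_helix(6)
  sigmas <- c(0, 0.01, 0.03, 0.08, 0.2)
  res <- vapply(sigmas, function(sg) {
    maps <- make_noisy_map(s, fixture_spec(n_residues = 6, noise_sigma = sg,
                                           seed = 11))
    resolution_at_threshold(fsc_curve(maps$noisy, maps$clean), 0.143)$resolution
  }, numeric(1))
  expect_true(all(diff(res) >= -1e-9))
})

test_that("percent improvement matches the worked examples", {
  expect_equal(percent_improvement(2.69, 1.95), 27.5, tolerance = 0.01)
  expect_equal(percent_improvement(4.01, 3.33), 16.96, tolerance = 0.01)
  expect_identical(percent_improvement(3.3, 3.3), 0)
  expect_error(percent_improvement(0, 1), "positive")
})

test_that("resolution summaries follow box-plot conventions", {
  s <- summarize_resolutions(c(2, 2, 2))
  expect_equal(s$mean, 2)
  expect_equal(s$iqr, 0)
  s2 <- summarize_resolutions(c(1, 2, 3, 4))
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$q1, 1.75)     # type-7 linear-interpolation quantiles
  expect_equal(s2$q3, 3.25)
  expect_equal(s2$whisker_high, 3.25 + 1.5 * 1.5)
  expect_equal(summarize_resolutions(3.1)$mean, 3.1)
  expect_error(summarize_resolutions(numeric(0)), "non-empty")
})
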