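TE <- echo_times()
tev <- as.numeric(TE)

test_that("noiseless decays are recovered exactly across the T2* range", {
  set.seed(101)
  for (i in 1:25) {
    T2 <- runif(1, 5, 500)
    S0 <- runif(1, 10, 1000)
    s <- S0 * exp(-tev / T2)
    init <- loglinear_init(s, TE)
    expect_true(init$converged)
    expect_equal(init$t2star, T2, tolerance = 1e-9)
    expect_equal(init$s0, S0, tolerance = 1e-9)
    fit <- fit_monoexponential(s, TE)
    expect_true(fit$converged)
    expect_equal(fit$t2star, T2, tolerance = 1e-6)
    expect_equal(fit$s0, S0, tolerance = 1e-6)
  }
})

test_that("degenerate signals are flagged, never force-fitted", {
  # constant positive signal: zero slope means infinite T2*
  expect_false(loglinear_init(rep(7, 5), TE)$converged)
  # positive at only one echo
  expect_false(loglinear_init(c(5, 0, 0, 0, 0), TE)$converged)
  # all-zero signal
  expect_false(loglinear_init(rep(0, 5), TE)$converged)
  expect_false(fit_monoexponential(rep(0, 5), TE)$converged)
  # rising signal has no decay solution
  expect_false(fit_monoexponential(c(1, 2, 3, 4, 5), TE)$converged)
})

test_that("noisy fits match an exhaustive SSE grid search", {
  set.seed(7)
  for (i in 1:5) {
    T2 <- runif(1, 40, 200); S0 <- runif(1, 50, 200)
    s <- pmax(S0 * exp(-tev / T2) * (1 + rnorm(5, sd = 0.02)), 0)
    fit <- fit_monoexponential(s, TE)
    g <- oracle_grid_fit(s, tev,
                         s0_grid = seq(S0 * 0.9, S0 * 1.1, length.out = 161),
                         t2_grid = seq(T2 * 0.8, T2 * 1.2, length.out = 161))
    expect_equal(fit$t2star, g$t2star,
                 tolerance = 2 * diff(range(T2 * c(0.8, 1.2))) / 160 / g$t2star)
    expect_equal(fit$s0, g$s0,
                 tolerance = 2 * (S0 * 0.2) / 160 / g$s0)
    expect_lte(fit$residual_sse, g$sse + 1e-9)
  }
})

test_that("nonlinear refinement never worsens the initializer's SSE", {
  set.seed(12)
  for (i in 1:40) {
    T2 <- runif(1, 10, 450); S0 <- runif(1, 10, 500)
    s <- pmax(S0 * exp(-tev / T2) + rnorm(5, sd = 0.1 * S0), 0)
    init <- loglinear_init(s, TE)
    if (!init$converged || init$t2star > 1000) next
    fit <- fit_monoexponential(s, TE)
    expect_lte(fit$residual_sse, init$residual_sse + 1e-10)
  }
})

test_that("estimator bias at SNR 20 matches the frozen oracle reference", {
  # Reference computed once with minpack.lm::nlsLM on 1000 seed-pinned
  # voxels (T2* 90 msec, S0 100, first-echo SNR 20): mean fitted T2*
  # 90.3457, Monte-Carlo SE 0.2651.
  ref_mean <- 90.345735
  ref_se <- 0.265128
  set.seed(777)
  n <- 1000; T2 <- 90; S0 <- 100
  sig <- S0 * exp(-11.2 / T2) / 20
  S <- pmax(matrix(rep(S0 * exp(-tev / T2), each = n), n) +
              matrix(rnorm(n * 5, sd = sig), n), 0)
  fit <- placentaflow:::fit_voxels(S, tev, cap = 1000)
  m <- mean(fit$t2star, na.rm = TRUE)
  se <- sd(fit$t2star, na.rm = TRUE) / sqrt(sum(fit$converged))
  expect_lt(abs(m - ref_mean), 3 * sqrt(se^2 + ref_se^2))
})

test_that("map fitting recovers a piecewise-constant field and honours the ROI", {
  geom <- voxel_geometry(c(10, 10, 6), c(2.5, 2.5, 2.5))
  truth <- array(60, dim = geom$dims)
  truth[6:10, , ] <- 140
  t2map <- scalar_map(truth, geom, "msec")
  s0map <- scalar_map(array(80, dim = geom$dims), geom, "signal")
  vol <- simulate_multiecho(t2map, s0map, TE, snr = Inf)
  maps <- fit_t2star_map(vol)
  expect_true(all(maps$t2star$validity == 1L))
  expect_equal(maps$t2star$data, truth, tolerance = 1e-6)
  expect_equal(maps$s0$data, s0map$data, tolerance = 1e-6)
  # empty ROI: everything invalid
  roi <- suppressWarnings(binary_mask(array(0, dim = geom$dims), geom))
  maps2 <- fit_t2star_map(vol, roi = roi)
  expect_true(all(maps2$t2star$validity == 0L))
  expect_true(all(is.na(maps2$t2star$data)))
  # masked fit only fills the ROI
  half <- array(0L, dim = geom$dims); half[1:5, , ] <- 1L
  roi3 <- binary_mask(half, geom)
  maps3 <- fit_t2star_map(vol, roi = roi3)
  expect_true(all(maps3$t2star$validity[half == 1L] == 1L))
  expect_true(all(maps3$t2star$validity[half == 0L] == 0L))
})

test_that("thresholded ROI mean matches the brute-force loop oracle", {
  geom <- voxel_geometry(c(6, 5, 4), c(2, 2, 3))
  set.seed(33)
  mask <- binary_mask(random_mask(geom$dims, 0.6), geom)
  vals <- array(runif(prod(geom$dims), 0, 800), dim = geom$dims)
  valid <- random_mask(geom$dims, 0.9)
  m <- scalar_map(ifelse(valid == 1L, vals, NA_real_), geom, "msec",
                  validity = valid)
  for (thr in c(100, 500, 900)) {
    expect_equal(mean_t2star(m, mask, thr),
                 oracle_mean_t2(m$data, valid, mask$data, thr),
                 tolerance = 1e-12)
  }
})

test_that("the 500 msec threshold excludes fluid-like voxels", {
  geom <- voxel_geometry(c(2, 1, 1))
  mask <- binary_mask(array(1, dim = c(2, 1, 1)), geom)
  m <- scalar_map(array(c(100, 600), dim = c(2, 1, 1)), geom, "msec")
  expect_equal(mean_t2star(m, mask), 100)
  # uniform map below threshold: the mean is that constant
  m2 <- scalar_map(array(42, dim = c(2, 1, 1)), geom, "msec")
  expect_equal(mean_t2star(m2, mask), 42)
  # nothing qualifies
  m3 <- scalar_map(array(c(600, 700), dim = c(2, 1, 1)), geom, "msec")
  expect_true(is.na(mean_t2star(m3, mask)))
  # grid mismatch is an error
  other <- binary_mask(array(1, dim = c(3, 1, 1)), voxel_geometry(c(3, 1, 1)))
  expect_error(mean_t2star(m, other), "grids")
})

test_that("mean T2* is monotone in the threshold", {
  geom <- voxel_geometry(c(8, 8, 4))
  set.seed(5)
  mask <- binary_mask(random_mask(geom$dims, 0.7), geom)
  m <- scalar_map(array(runif(prod(geom$dims), 10, 900), dim = geom$dims),
                  geom, "msec")
  thrs <- c(50, 150, 300, 500, 950)
  counts <- vapply(thrs, function(t) {
    sum(mask$data == 1L & m$data < t)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # raising the threshold only ever adds (larger) values
  means <- vapply(thrs, function(t) mean_t2star(m, mask, t), numeric(1))
  expect_true(all(diff(means[is.finite(means)]) >= 0))
})
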