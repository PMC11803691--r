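small_sp <- function(...) {
  args <- utils::modifyList(
    list(dims = c(24L, 24L, 24L), placenta_radius_mm = 16,
         placenta_thickness_mm = 12, boundary_amplitude_mm = 2,
         boundary_wavelength_mm = 20, brain_radii_mm = c(9, 8, 7)),
    list(...))
  do.call(phantom_spec, args)
}

test_that("phantom generation is fully determined by spec and seed", {
  a <- make_phantom(small_sp(seed = 9))
  b <- make_phantom(small_sp(seed = 9))
  expect_identical(a$placenta_mask$data, b$placenta_mask$data)
  expect_identical(a$brain_mask$data, b$brain_mask$data)
  expect_identical(a$truth$t2star$data, b$truth$t2star$data)
  expect_identical(a$volume$data, b$volume$data)
  c_ <- make_phantom(small_sp(seed = 10))
  expect_false(identical(a$volume$data, c_$volume$data))
})

test_that("an unperturbed placenta is a symmetric disc with the analytic score", {
  sp <- small_sp(boundary_amplitude_mm = 0, seed = 2)
  pm <- make_placenta_mask(sp)
  m <- pm$data
  # rotational symmetry: invariant under in-plane flips about the centre
  expect_identical(m, m[rev(seq_len(24)), , ])
  expect_identical(m, m[, rev(seq_len(24)), ])
  # morphology agrees with the brute-force EDT on the same small grid
  ref <- oracle_edt(m, sp$spacing)
  vals <- ref[m == 1L]
  score_ref <- mean(vals) + sqrt(mean((vals - mean(vals))^2))
  d <- distance_map(pm)
  expect_equal(morphology_score(d, pm), score_ref, tolerance = 1e-12)
})

test_that("boundary perturbation amplitude drives the morphology score up", {
  # levels spaced beyond the 2.5 mm voxel quantum so each step can move
  # the discretized surface
  amps <- c(0, 3, 6, 9, 12)
  scores <- vapply(amps, function(a) {
    sp <- phantom_spec(boundary_amplitude_mm = a, seed = 31)
    mm <- morphology_metrics(make_placenta_mask(sp))
    mm$morphology_score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("T2* fields honour mean, heterogeneity and clipping", {
  sp <- small_sp(seed = 12, placenta_t2_sd = 15)
  pm <- make_placenta_mask(sp)
  f <- make_t2star_field(sp, pm)
  v <- f$data[pm$data == 1L]
  expect_true(all(is.finite(v)))
  expect_true(all(v >= 5 & v <= 450))
  n_eff <- sum(pm$data)  # correlated field: crude SE bound uses raw n
  expect_lt(abs(mean(v) - sp$placenta_t2_mean), 3 * 15 / sqrt(n_eff / 30))
  expect_equal(sd(v), 15, tolerance = 0.05)
  # zero heterogeneity collapses to the constant mean
  sp0 <- small_sp(seed = 12, placenta_t2_sd = 0)
  f0 <- make_t2star_field(sp0, pm)
  expect_true(all(f0$data[pm$data == 1L] == sp0$placenta_t2_mean))
})

test_that("longer field correlation length yields smoother texture", {
  lens <- c(2.5, 5, 7.5, 10, 15)
  tex <- vapply(lens, function(cl) {
    sp <- phantom_spec(placenta_corr_length_mm = cl, seed = 13,
                       snr_echo1 = Inf)
    pm <- make_placenta_mask(sp)
    placental_texture(make_t2star_field(sp, pm), pm)
  }, numeric(1))
  expect_true(all(diff(tex) > 0))
})

test_that("the forward model is linear in S0 and exactly invertible", {
  sp <- small_sp(seed = 14, snr_echo1 = Inf)
  ph <- make_phantom(sp)
  # doubling S0 doubles the noiseless signal at every echo
  s0_twice <- scalar_map(ph$truth$s0$data * 2, ph$truth$s0$geometry, "signal")
  v2 <- simulate_multiecho(ph$truth$t2star, s0_twice, echo_times())
  expect_equal(v2$data, 2 * ph$volume$data, tolerance = 1e-12)
  # noiseless inverse-of-forward identity through the fit
  maps <- fit_t2star_map(ph$volume, roi = ph$placenta_mask)
  sel <- ph$placenta_mask$data == 1L
  rel <- abs(maps$t2star$data[sel] - ph$truth$t2star$data[sel]) /
    ph$truth$t2star$data[sel]
  expect_lt(max(rel), 1e-6)
})

test_that("noise is reproducible and scaled to the first-echo SNR", {
  sp <- small_sp(seed = 15, snr_echo1 = 20)
  ph1 <- make_phantom(sp)
  ph2 <- make_phantom(sp)
  expect_identical(ph1$volume$data, ph2$volume$data)
  noiseless <- make_phantom(small_sp(seed = 15, snr_echo1 = Inf))
  resid <- ph1$volume$data - noiseless$volume$data
  pm <- noiseless$placenta_mask
  mean_e1 <- mean(noiseless$volume$data[, , , 1][pm$data == 1L])
  # truncation at zero only affects late, low-signal echoes appreciably
  sd_e1 <- sd(resid[, , , 1])
  expect_equal(sd_e1, mean_e1 / 20, tolerance = 0.02)
})

test_that("cohort generation is deterministic and carries ground truth", {
  spec <- cohort_spec(seed = 100)
  g1 <- generate_cohort(spec)
  g2 <- generate_cohort(spec)
  expect_identical(g1$table, g2$table)
  expect_equal(nrow(g1$table), 81)
  expect_equal(sum(g1$table$group == "control"), 30)
  expect_length(g1$ground_truth$latent, 81)
  expect_length(g1$ground_truth$placenta_true, 81)
  # GA confounding present by default: controls scanned later
  expect_gt(median(g1$table$ga_weeks[g1$table$group == "control"]),
            median(g1$table$ga_weeks[g1$table$group == "CHD"]))
})

test_that("default cohorts reproduce the qualitative effect structure", {
  g <- generate_cohort(cohort_spec(seed = 7))
  rep <- run_statistics(g$table)
  ga <- rep$ga_correlations
  pooled <- function(m) ga$rho[ga$metric == m & ga$subset == "all"]
  expect_lt(pooled("placenta_t2"), 0)
  expect_lt(pooled("brain_t2"), 0)
  expect_gt(pooled("volume_mm3"), 0)
  gc <- rep$group_comparisons
  expect_lt(gc$estimate[gc$metric == "placenta_t2"], 0)
  expect_lt(gc$estimate[gc$metric == "brain_t2"], 0)
  expect_lt(gc$estimate[gc$metric == "texture"], 0)
  expect_gt(gc$estimate[gc$metric == "morphology"], 0)
  pc <- rep$partial_correlations
  expect_gt(pc$estimate[pc$panel == "brain_vs_placenta" &
                          pc$subset == "all" &
                          pc$test == "partial_spearman"], 0)
})

test_that("image mode agrees with the table-mode generative means", {
  spec <- cohort_spec(n_control = 2L, n_chd = 2L, seed = 21)
  ph <- phantom_spec(dims = c(32L, 32L, 32L), placenta_radius_mm = 24,
                     placenta_thickness_mm = 18, boundary_amplitude_mm = 2,
                     boundary_wavelength_mm = 30, brain_radii_mm = c(12, 10, 9),
                     snr_echo1 = 50)
  g <- generate_cohort(spec, mode = "image", phantom = ph)
  expect_equal(nrow(g$table), 4)
  truth_p <- pmin(pmax(g$ground_truth$placenta_true, 20), 440)
  truth_b <- pmin(pmax(g$ground_truth$brain_true, 20), 440)
  # measured ROI means track the per-subject generative organ means
  expect_lt(max(abs(g$table$placenta_t2 - truth_p)), 4)
  expect_lt(max(abs(g$table$brain_t2 - truth_b)), 4)
  expect_true(all(is.finite(g$table$morphology)))
  expect_true(all(is.finite(g$table$texture)))
})
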