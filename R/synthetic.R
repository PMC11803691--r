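#' Phantom specification
#'
#' Parameters of the digital phantom: a perturbed-disc placenta and an
#' ellipsoidal fetal-brain surrogate embedded in fluid, on a 2.5 mm
#' isotropic grid, imaged with the 5-echo protocol (TE = 11.2 to 194.7
#' msec). Defaults give a placenta-like organ (radius 45 mm, base thickness
#' 34 mm, gently lobulated boundary) with a spatially correlated T2* field
#' around 90 msec, a brain surrogate around 210 msec, and fluid above the
#' 500 msec reporting threshold.
#'
#' @param dims Grid dims (default 64^3).
#' @param spacing Voxel spacing, mm (default 2.5 isotropic).
#' @param placenta_radius_mm,placenta_thickness_mm Disc radius and base
#'   thickness, mm.
#' @param boundary_amplitude_mm Amplitude of the smooth sinusoidal boundary
#'   perturbation, mm; 0 gives a rotationally symmetric disc.
#' @param boundary_wavelength_mm In-plane wavelength of the thickness
#'   modulation, mm.
#' @param brain_radii_mm Ellipsoid semi-axes, mm.
#' @param placenta_t2_mean,placenta_t2_sd Placental T2* field mean and
#'   heterogeneity SD, msec.
#' @param placenta_corr_length_mm Correlation length (Gaussian smoothing
#'   sigma) of the placental T2* field, mm — the lobule scale.
#' @param brain_t2_mean,brain_t2_sd Brain T2* field mean and SD, msec.
#' @param fluid_t2 Background fluid T2*, msec; must exceed the 500 msec
#'   reporting threshold so fluid is excluded from ROI means.
#' @param s0_level Proton-density signal level (arbitrary units).
#' @param snr_echo1 First-echo SNR of the simulated acquisition.
#' @param seed Integer seed; a (spec, seed) pair fully determines the
#'   phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(64L, 64L, 64L), spacing = c(2.5, 2.5, 2.5),
                         placenta_radius_mm = 45, placenta_thickness_mm = 34,
                         boundary_amplitude_mm = 4,
                         boundary_wavelength_mm = 40,
                         brain_radii_mm = c(30, 25, 22),
                         placenta_t2_mean = 90, placenta_t2_sd = 15,
                         placenta_corr_length_mm = 7.5,
                         brain_t2_mean = 210, brain_t2_sd = 8,
                         fluid_t2 = 600, s0_level = 100,
                         snr_echo1 = 20, seed = 1L) {
  spec <- list(dims = as.integer(dims), spacing = as.numeric(spacing),
               placenta_radius_mm = placenta_radius_mm,
               placenta_thickness_mm = placenta_thickness_mm,
               boundary_amplitude_mm = boundary_amplitude_mm,
               boundary_wavelength_mm = boundary_wavelength_mm,
               brain_radii_mm = brain_radii_mm,
               placenta_t2_mean = placenta_t2_mean,
               placenta_t2_sd = placenta_t2_sd,
               placenta_corr_length_mm = placenta_corr_length_mm,
               brain_t2_mean = brain_t2_mean, brain_t2_sd = brain_t2_sd,
               fluid_t2 = fluid_t2, s0_level = s0_level,
               snr_echo1 = snr_echo1, seed = as.integer(seed))
  stopifnot(all(spec$dims >= 8), all(spec$spacing > 0),
            spec$placenta_radius_mm > 0, spec$placenta_thickness_mm > 0,
            spec$boundary_amplitude_mm >= 0, spec$snr_echo1 > 0,
            spec$fluid_t2 > 500)
  class(spec) <- "phantom_spec"
  spec
}

phantom_geometry <- function(spec) voxel_geometry(spec$dims, spec$spacing)

voxel_centres <- function(spec) {
  list(x = (seq_len(spec$dims[1]) - 0.5) * spec$spacing[1],
       y = (seq_len(spec$dims[2]) - 0.5) * spec$spacing[2],
       z = (seq_len(spec$dims[3]) - 0.5) * spec$spacing[3])
}

#' Generate the phantom placental mask
#'
#' A voxelized disc of fixed radius whose thickness (the chorionic and
#' basal surfaces) carries a smooth half-cosine dome of the stated
#' amplitude and half-width, centred at a seed-random in-plane position.
#' Amplitude 0 yields a rotationally symmetric disc; larger amplitudes
#' produce a bulkier, less uniformly shaped organ, which raises the
#' morphology score: the dome adds interior bulk (and a deeper distance
#' maximum) while leaving the rim untouched.
#'
#' @param spec A [phantom_spec].
#' @return A placental [binary_mask].
#' @export
make_placenta_mask <- function(spec) {
  ext <- spec$dims * spec$spacing
  reach_r <- spec$placenta_radius_mm
  reach_z <- (spec$placenta_thickness_mm + spec$boundary_amplitude_mm) / 2
  cx <- ext[1] / 2; cy <- ext[2] / 2; cz <- ext[3] * 0.3
  if (reach_r + spec$spacing[1] > min(cx, cy) ||
      reach_z + spec$spacing[3] > min(cz, ext[3] - cz)) {
    stop("make_placenta_mask: placenta does not fit on the grid",
         call. = FALSE)
  }
  ph <- with_seed(spec$seed, runif(2))
  cc <- voxel_centres(spec)
  X <- outer(cc$x - cx, rep(1, spec$dims[2]))
  Y <- outer(rep(1, spec$dims[1]), cc$y - cy)
  r <- sqrt(X^2 + Y^2)
  a <- spec$boundary_amplitude_mm
  # one smooth dome-shaped bulge of half-width boundary_wavelength_mm,
  # centred at a seed-random in-plane position inside the disc
  bump_r <- ph[1] * spec$placenta_radius_mm / 3
  bump_th <- ph[2] * 2 * pi
  bx <- bump_r * cos(bump_th); by <- bump_r * sin(bump_th)
  db <- sqrt((X - bx)^2 + (Y - by)^2)
  bump <- cos(pi / 2 * pmin(db / spec$boundary_wavelength_mm, 1))^2
  thick_xy <- pmax(spec$placenta_thickness_mm + a * bump,
                   spec$spacing[3])
  inside_xy <- r <= spec$placenta_radius_mm
  m <- array(0L, dim = spec$dims)
  for (k in seq_len(spec$dims[3])) {
    dz <- abs(cc$z[k] - cz)
    m[, , k] <- as.integer(inside_xy & dz <= thick_xy / 2)
  }
  binary_mask(m, phantom_geometry(spec), "placenta")
}

#' Generate the phantom brain mask
#'
#' Ellipsoid of the spec's semi-axes, placed clear of the placenta.
#'
#' @param spec A [phantom_spec].
#' @return A brain [binary_mask].
#' @export
make_brain_mask <- function(spec) {
  ext <- spec$dims * spec$spacing
  cx <- ext[1] / 2; cy <- ext[2] / 2; cz <- ext[3] * 0.72
  rad <- spec$brain_radii_mm
  if (rad[1] + spec$spacing[1] > cx || rad[2] + spec$spacing[2] > cy ||
      rad[3] + spec$spacing[3] > min(cz, ext[3] - cz)) {
    stop("make_brain_mask: brain ellipsoid does not fit on the grid",
         call. = FALSE)
  }
  cc <- voxel_centres(spec)
  m <- array(0L, dim = spec$dims)
  xs2 <- ((cc$x - cx) / rad[1])^2
  ys2 <- ((cc$y - cy) / rad[2])^2
  for (k in seq_len(spec$dims[3])) {
    zs2 <- ((cc$z[k] - cz) / rad[3])^2
    m[, , k] <- as.integer(outer(xs2, ys2, `+`) + zs2 <= 1)
  }
  binary_mask(m, phantom_geometry(spec), "brain")
}

# Separable Gaussian smoothing with sigma in mm (anisotropy-aware); dense
# per-axis kernel matrices are cheap at these grid sizes.
gaussian_smooth3d <- function(arr, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(arr)
  d <- dim(arr)
  for (ax in 1:3) {
    n <- d[ax]
    pos <- seq_len(n) * spacing[ax]
    K <- exp(-outer(pos, pos, `-`)^2 / (2 * sigma_mm^2))
    K <- K / rowSums(K)
    arr <- switch(ax,
      {m <- K %*% matrix(arr, nrow = d[1]); array(m, dim = d)},
      {p <- aperm(arr, c(2, 1, 3))
       m <- K %*% matrix(p, nrow = d[2])
       aperm(array(m, dim = d[c(2, 1, 3)]), c(2, 1, 3))},
      {p <- aperm(arr, c(3, 1, 2))
       m <- K %*% matrix(p, nrow = d[3])
       aperm(array(m, dim = d[c(3, 1, 2)]), c(2, 3, 1))})
  }
  arr
}

#' Generate a spatially correlated T2* field inside a mask
#'
#' Smoothed, renormalised Gaussian white noise: target mean and
#' heterogeneity SD with the stated correlation length (the lobule scale),
#' clipped to (5, 450) msec. SD 0 returns the constant mean.
#'
#' @param spec A [phantom_spec]; mean/SD/correlation length are taken for
#'   the organ named by `mask$label`.
#' @param mask A [binary_mask].
#' @param seed_offset Added to the spec seed so the placenta and brain
#'   fields draw independent noise.
#' @return A [scalar_map] (msec), valid inside the mask.
#' @export
make_t2star_field <- function(spec, mask, seed_offset = 0L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask$label == "placenta") {
    mu <- spec$placenta_t2_mean; s <- spec$placenta_t2_sd
    cl <- spec$placenta_corr_length_mm
  } else {
    mu <- spec$brain_t2_mean; s <- spec$brain_t2_sd
    cl <- spec$placenta_corr_length_mm
  }
  inside <- mask$data == 1L
  f <- array(NA_real_, dim = spec$dims)
  if (s <= 0) {
    f[inside] <- mu
  } else {
    noise <- with_seed(spec$seed + seed_offset,
                       array(rnorm(prod(spec$dims)), dim = spec$dims))
    sm <- gaussian_smooth3d(noise, cl, spec$spacing)
    v <- sm[inside]
    sdv <- sd(v)
    if (sdv == 0) {
      f[inside] <- mu
    } else {
      f[inside] <- pmin(pmax((v - mean(v)) / sdv * s + mu, 5), 450)
    }
  }
  scalar_map(f, phantom_geometry(spec), "msec", validity = mask$data)
}

#' Simulate a multi-echo acquisition from ground-truth maps
#'
#' Forward mono-exponential model S(TE) = S0 exp(-TE/T2*) per echo, plus
#' zero-mean Gaussian noise whose SD is the mean first-echo signal over the
#' reference voxels divided by `snr`; negative samples are truncated at 0
#' (magnitude data). Gaussian rather than Rician noise is a documented
#' simplification, adequate at the simulated SNR (>= 10).
#'
#' @param t2star_truth,s0_truth Ground-truth [scalar_map]s on one grid;
#'   voxels invalid in either map produce zero signal.
#' @param echoes An [echo_times].
#' @param snr First-echo SNR; `Inf` for a noiseless acquisition.
#' @param seed Integer seed (noise is deterministic given it).
#' @param reference Optional [binary_mask]; the first-echo signal mean that
#'   defines the noise SD is taken over this mask (default: all validly
#'   modelled voxels).
#' @return A [multiecho_volume].
#' @export
simulate_multiecho <- function(t2star_truth, s0_truth, echoes, snr = Inf,
                               seed = 1L, reference = NULL) {
  stopifnot(inherits(t2star_truth, "scalar_map"),
            inherits(s0_truth, "scalar_map"),
            inherits(echoes, "echo_times"))
  if (!same_grid(t2star_truth$geometry, s0_truth$geometry)) {
    stop("simulate_multiecho: maps on different grids", call. = FALSE)
  }
  d <- t2star_truth$geometry$dims
  te <- as.numeric(echoes)
  ok <- t2star_truth$validity == 1L & s0_truth$validity == 1L
  t2 <- ifelse(ok, t2star_truth$data, NA_real_)
  s0 <- ifelse(ok, s0_truth$data, NA_real_)
  vol <- array(0, dim = c(d, length(te)))
  for (e in seq_along(te)) {
    sl <- s0 * exp(-te[e] / t2)
    sl[!ok] <- 0
    vol[, , , e] <- sl
  }
  if (is.finite(snr)) {
    ref_sel <- if (is.null(reference)) ok else (reference$data == 1L & ok)
    ref <- vol[, , , 1][ref_sel]
    sigma <- mean(ref) / snr
    noise <- with_seed(seed, array(rnorm(length(vol), sd = sigma),
                                   dim = dim(vol)))
    vol <- pmax(vol + noise, 0)
  }
  multiecho_volume(vol, echoes, t2star_truth$geometry)
}

#' Render a complete phantom subject
#'
#' Builds the placental and brain masks, organ T2* fields over a fluid
#' background (fluid T2* above the reporting threshold, so it is excluded
#' from ROI means exactly as amniotic fluid and CSF are in vivo), a uniform
#' S0 map, and the simulated multi-echo volume.
#'
#' @param spec A [phantom_spec].
#' @param echoes An [echo_times] (default the 5-echo protocol).
#' @return List: `volume`, `placenta_mask`, `brain_mask`, and `truth`
#'   (ground-truth `t2star` and `s0` maps plus the spec).
#' @export
make_phantom <- function(spec, echoes = echo_times()) {
  geom <- phantom_geometry(spec)
  pm <- make_placenta_mask(spec)
  bm <- make_brain_mask(spec)
  if (any(pm$data == 1L & bm$data == 1L)) {
    stop("make_phantom: placenta and brain masks overlap", call. = FALSE)
  }
  pf <- make_t2star_field(spec, pm, seed_offset = 1L)
  bf <- make_t2star_field(spec, bm, seed_offset = 2L)
  t2 <- array(spec$fluid_t2, dim = spec$dims)
  t2[pm$data == 1L] <- pf$data[pm$data == 1L]
  t2[bm$data == 1L] <- bf$data[bm$data == 1L]
  t2map <- scalar_map(t2, geom, "msec")
  s0map <- scalar_map(array(spec$s0_level, dim = spec$dims), geom, "signal")
  vol <- simulate_multiecho(t2map, s0map, echoes, snr = spec$snr_echo1,
                            seed = spec$seed + 3L, reference = pm)
  list(volume = vol, placenta_mask = pm, brain_mask = bm,
       truth = list(t2star = t2map, s0 = s0map, spec = spec))
}

#' Cohort specification
#'
#' Generative model of the study cohort. Gestational ages are drawn per
#' group from truncated normals matching the study's demographics (control
#' median 34.5, IQR 31.9-36.7 weeks; CHD median 32.0, IQR 30.9-32.9), so GA
#' confounding between groups is present by default and the ANCOVA
#' adjustment is exercised. Organ-level true mean T2* follows
#' intercept + slope * GA + group offset + loading * latent + noise, with a
#' single shared standard-normal latent factor producing the brain-placenta
#' association. Default slopes, offsets and scales are set so pooled
#' moments echo the study's printed summaries (placental T2* ~97 vs ~83
#' msec; brain ~218 vs ~202; negative GA trends; positive latent
#' correlation).
#'
#' @param n_control,n_chd Group sizes (default 30 and 51).
#' @param ga_control,ga_chd `c(mean, sd)` of the truncated-normal GA
#'   distribution per group, weeks.
#' @param ga_range Truncation bounds, weeks.
#' @param placenta,brain Lists with `intercept`, `slope` (msec/week),
#'   `offset` (CHD minus control, msec), `loading` (latent factor, msec),
#'   `sd` (residual msec).
#' @param volume List with `intercept`, `slope`, `offset`, `sd` on the
#'   study's printed volume scale.
#' @param texture,morphology,thickness Lists with `mean`, `offset`, `sd`.
#' @param maternal_age `c(mean, sd)` years, shared by both groups.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_control = 30L, n_chd = 51L,
                        ga_control = c(34.5, 3.56), ga_chd = c(32.0, 1.48),
                        ga_range = c(28, 40),
                        placenta = list(intercept = 269.5, slope = -5,
                                        offset = -14, loading = 12, sd = 14),
                        brain = list(intercept = 321.5, slope = -3,
                                     offset = -16, loading = 13, sd = 15),
                        volume = list(intercept = -59, slope = 18,
                                      offset = 46, sd = 200),
                        texture = list(mean = 0.845, offset = -0.04,
                                       sd = 0.03),
                        morphology = list(mean = 9.9, offset = 0.9,
                                          sd = 2.2),
                        thickness = list(mean = 38.7, offset = 1.8,
                                         sd = 8.2),
                        maternal_age = c(33, 5), seed = 1L) {
  spec <- list(n_control = as.integer(n_control), n_chd = as.integer(n_chd),
               ga_control = ga_control, ga_chd = ga_chd, ga_range = ga_range,
               placenta = placenta, brain = brain, volume = volume,
               texture = texture, morphology = morphology,
               thickness = thickness, maternal_age = maternal_age,
               seed = as.integer(seed))
  stopifnot(spec$n_control >= 2, spec$n_chd >= 2,
            ga_range[1] > 20, ga_range[2] < 45)
  class(spec) <- "cohort_spec"
  spec
}

#' Null cohort specification
#'
#' The calibration scenario: no GA slopes, no group offsets, no latent
#' correlation; both groups draw GA from the pooled distribution. Every
#' between-group and partial-correlation test should then reject at the
#' nominal rate.
#'
#' @param seed Integer seed.
#' @param n_control,n_chd Group sizes.
#' @return A `cohort_spec`.
#' @export
null_cohort_spec <- function(seed = 1L, n_control = 30L, n_chd = 51L) {
  cohort_spec(
    n_control = n_control, n_chd = n_chd,
    ga_control = c(33, 3), ga_chd = c(33, 3),
    placenta = list(intercept = 97, slope = 0, offset = 0, loading = 0,
                    sd = 20),
    brain = list(intercept = 210, slope = 0, offset = 0, loading = 0,
                 sd = 20),
    volume = list(intercept = 580, slope = 0, offset = 0, sd = 200),
    texture = list(mean = 0.82, offset = 0, sd = 0.03),
    morphology = list(mean = 10.3, offset = 0, sd = 2.1),
    thickness = list(mean = 39.5, offset = 0, sd = 8.1),
    seed = seed
  )
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic cohort with full ground truth
#'
#' Table mode draws metric-level records directly from the generative model
#' (fast; used by the calibration and power studies). Image mode renders a
#' phantom per subject whose organ T2* fields are centred on the subject's
#' generative means, runs the full image pipeline on it, and fills the
#' table from the measured metrics (texture, morphology, thickness and
#' volume then come from the shared phantom geometry, not from group
#' shifts).
#'
#' @param spec A [cohort_spec].
#' @param mode `"table"` or `"image"`.
#' @param phantom Base [phantom_spec] for image mode.
#' @param config Run configuration ([run_config()]) for image mode.
#' @return List with `table` (cohort data.frame) and `ground_truth`
#'   (per-subject latent factors, true organ means, and the spec).
#' @export
generate_cohort <- function(spec, mode = c("table", "image"),
                            phantom = phantom_spec(), config = run_config()) {
  mode <- match.arg(mode)
  n <- spec$n_control + spec$n_chd
  group <- c(rep("control", spec$n_control), rep("CHD", spec$n_chd))
  truth <- with_seed(spec$seed, {
    ga <- c(rtruncnorm(spec$n_control, spec$ga_control[1], spec$ga_control[2],
                       spec$ga_range[1], spec$ga_range[2]),
            rtruncnorm(spec$n_chd, spec$ga_chd[1], spec$ga_chd[2],
                       spec$ga_range[1], spec$ga_range[2]))
    mat_age <- pmin(pmax(rnorm(n, spec$maternal_age[1], spec$maternal_age[2]),
                         18), 50)
    latent <- rnorm(n)
    chd <- as.numeric(group == "CHD")
    p <- spec$placenta
    b <- spec$brain
    placenta_true <- p$intercept + p$slope * ga + p$offset * chd +
      p$loading * latent
    brain_true <- b$intercept + b$slope * ga + b$offset * chd +
      b$loading * latent
    list(ga = ga, mat_age = mat_age, latent = latent,
         placenta_true = placenta_true, brain_true = brain_true,
         placenta_obs = placenta_true + rnorm(n, sd = p$sd),
         brain_obs = brain_true + rnorm(n, sd = b$sd),
         volume = pmax(spec$volume$intercept + spec$volume$slope * ga +
                         spec$volume$offset * chd +
                         rnorm(n, sd = spec$volume$sd), 50),
         texture = pmin(pmax(spec$texture$mean + spec$texture$offset * chd +
                               rnorm(n, sd = spec$texture$sd), -1), 1),
         morphology = pmax(spec$morphology$mean +
                             spec$morphology$offset * chd +
                             rnorm(n, sd = spec$morphology$sd), 0.1),
         thickness = pmax(spec$thickness$mean + spec$thickness$offset * chd +
                            rnorm(n, sd = spec$thickness$sd), 1))
  })
  ids <- sprintf("sub-%03d", seq_len(n))
  if (mode == "table") {
    table <- data.frame(
      id = ids, group = group, ga_weeks = truth$ga,
      maternal_age_years = truth$mat_age,
      placenta_t2 = truth$placenta_obs, brain_t2 = truth$brain_obs,
      volume_mm3 = truth$volume, texture = truth$texture,
      morphology = truth$morphology, thickness_mm = truth$thickness,
      stringsAsFactors = FALSE)
  } else {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ps <- phantom
      ps$placenta_t2_mean <- min(max(truth$placenta_true[i], 20), 440)
      ps$brain_t2_mean <- min(max(truth$brain_true[i], 20), 440)
      ps$seed <- spec$seed + 1000L + i
      subj <- make_phantom(ps)
      rec <- run_subject(subj$volume, subj$placenta_mask, subj$brain_mask,
                         config = config,
                         id = ids[i], group = group[i],
                         ga_weeks = truth$ga[i],
                         maternal_age_years = truth$mat_age[i])
      rows[[i]] <- rec
    }
    table <- do.call(rbind, rows)
  }
  validate_cohort(table)
  list(table = table, ground_truth = c(truth, list(spec = spec,
                                                   group = group,
                                                   mode = mode)))
}
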