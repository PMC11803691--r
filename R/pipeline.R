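#' Process one subject: maps, metrics, record
#'
#' Fits the T2* map inside the union of the two organ masks, then computes
#' the placental metrics (thresholded mean T2*, volume, texture, morphology
#' score, maximum thickness) and the brain mean T2*. Any stage failure
#' flags the affected metrics as missing and the run continues — a subject
#' with an unusable brain mask still yields its placental metrics.
#'
#' @param volume A [multiecho_volume].
#' @param placenta_mask,brain_mask [binary_mask]s on the volume grid.
#' @param config Run configuration ([run_config()]): reporting threshold,
#'   fit cap, texture parameters.
#' @param id,group,ga_weeks,maternal_age_years Subject covariates.
#' @param keep_maps If TRUE, attach the fitted maps as an attribute.
#' @return One-row cohort data.frame (see [subject_record()]); failed
#'   metrics are `NA`.
#' @export
run_subject <- function(volume, placenta_mask, brain_mask,
                        config = run_config(), id = "sub-001",
                        group = "control", ga_weeks = NA_real_,
                        maternal_age_years = NA_real_, keep_maps = FALSE) {
  stopifnot(inherits(volume, "multiecho_volume"))
  roi <- NULL
  p_ok <- inherits(placenta_mask, "binary_mask") &&
    !is_empty_mask(placenta_mask)
  b_ok <- inherits(brain_mask, "binary_mask") && !is_empty_mask(brain_mask)
  if (p_ok || b_ok) {
    u <- array(0L, dim = volume$geometry$dims)
    if (p_ok) u[placenta_mask$data == 1L] <- 1L
    if (b_ok) u[brain_mask$data == 1L] <- 1L
    roi <- suppressWarnings(binary_mask(u, volume$geometry, "placenta"))
  }
  maps <- tryCatch(fit_t2star_map(volume, roi = roi, cap = config$cap_msec),
                   error = function(e) NULL)

  placenta_t2 <- brain_t2 <- volume_mm3 <- texture <-
    morphology <- thickness_mm <- NA_real_
  if (!is.null(maps) && p_ok) {
    placenta_t2 <- tryCatch(
      mean_t2star(maps$t2star, placenta_mask, config$threshold_msec),
      error = function(e) NA_real_)
    volume_mm3 <- tryCatch(mask_volume(placenta_mask),
                           error = function(e) NA_real_)
    texture <- tryCatch(
      placental_texture(maps$t2star, placenta_mask,
                        n_levels = config$texture$n_levels,
                        lo_pct = config$texture$lo_pct,
                        hi_pct = config$texture$hi_pct,
                        threshold = config$threshold_msec),
      error = function(e) NA_real_)
    mm <- tryCatch(morphology_metrics(placenta_mask),
                   error = function(e) NULL)
    if (!is.null(mm)) {
      morphology <- mm$morphology_score
      thickness_mm <- mm$max_thickness_mm
    }
  }
  if (!is.null(maps) && b_ok) {
    brain_t2 <- tryCatch(
      mean_t2star(maps$t2star, brain_mask, config$threshold_msec),
      error = function(e) NA_real_)
  }
  rec <- subject_record(id = id, group = group, ga_weeks = ga_weeks,
                        maternal_age_years = maternal_age_years,
                        placenta_t2 = placenta_t2, brain_t2 = brain_t2,
                        volume_mm3 = volume_mm3, texture = texture,
                        morphology = morphology,
                        thickness_mm = thickness_mm)
  if (keep_maps) attr(rec, "maps") <- maps
  rec
}

#' Process one subject from files on disk
#'
#' @param image,sidecar,placenta_mask,brain_mask Input paths (4D NIfTI,
#'   JSON sidecar, two 3D mask NIfTIs).
#' @param config Run configuration.
#' @param ... Covariates passed to [run_subject()].
#' @return One-row cohort data.frame.
#' @export
run_subject_files <- function(image, sidecar, placenta_mask, brain_mask,
                              config = run_config(), ...) {
  vol <- read_multiecho(image, sidecar)
  pm <- tryCatch(
    suppressWarnings(read_mask(placenta_mask, vol$geometry, "placenta")),
    error = function(e) NULL)
  bm <- tryCatch(
    suppressWarnings(read_mask(brain_mask, vol$geometry, "brain")),
    error = function(e) NULL)
  run_subject(vol, pm, bm, config = config, ...)
}

#' Run the whole cohort pipeline from a file manifest
#'
#' The manifest CSV lists one subject per row with columns id, group,
#' ga_weeks, maternal_age_years, image, sidecar, placenta_mask, brain_mask
#' (paths relative to the manifest's directory or absolute). Each subject is
#' processed with [run_subject_files()]; failures are flagged and skipped,
#' and the statistics stage runs on the assembled table.
#'
#' @param manifest Path to the manifest CSV, or a data.frame of the same
#'   shape.
#' @param config Run configuration; if `config$output_dir` is set, the
#'   cohort table and the statistics report are written there.
#' @param plan Analysis plan for [run_statistics()].
#' @return List with `table` and `report`.
#' @export
run_cohort <- function(manifest, config = run_config(), plan = stats_plan()) {
  if (is.character(manifest)) {
    base <- dirname(manifest)
    man <- read.csv(manifest, stringsAsFactors = FALSE)
  } else {
    base <- "."
    man <- manifest
  }
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    rows[[i]] <- tryCatch(
      run_subject_files(resolve(man$image[i]), resolve(man$sidecar[i]),
                        resolve(man$placenta_mask[i]),
                        resolve(man$brain_mask[i]),
                        config = config, id = man$id[i],
                        group = man$group[i], ga_weeks = man$ga_weeks[i],
                        maternal_age_years = man$maternal_age_years[i]),
      error = function(e) {
        warning(sprintf("subject %s failed: %s", man$id[i], conditionMessage(e)),
                call. = FALSE)
        NULL
      })
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("run_cohort: all subjects failed", call. = FALSE)
  table <- do.call(rbind, rows)
  validate_cohort(table)
  report <- run_statistics(table, plan)
  report$meta$seed <- config$seed
  report$meta$config <- config[c("threshold_msec", "cap_msec", "texture")]
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_table(table, file.path(config$output_dir, "cohort.csv"))
    write_stats_report(report, config$output_dir)
  }
  list(table = table, report = report)
}
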