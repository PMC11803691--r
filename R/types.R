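#' Echo-time vector
#'
#' Validated container for the echo times of a multi-echo gradient-echo
#' acquisition, in milliseconds. The default is the 5-echo protocol used
#' throughout this package: TE = (11.2, 57.1, 102.9, 148.8, 194.7) msec.
#'
#' @param values Numeric vector of echo times in msec; length >= 2, strictly
#'   increasing, all positive.
#' @return An object of class `echo_times` (a numeric vector).
#' @export
echo_times <- function(values = c(11.2, 57.1, 102.9, 148.8, 194.7)) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("echo_times: at least 2 echo times are required", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("echo_times: all echo times must be finite and > 0", call. = FALSE)
  }
  if (any(diff(values) <= 0)) {
    stop("echo_times: echo times must be strictly increasing", call. = FALSE)
  }
  structure(values, class = "echo_times")
}

#' Voxel grid geometry
#'
#' @param dims Integer triple (nx, ny, nz), all >= 1.
#' @param spacing Numeric triple of voxel spacings in mm (default 2.5 mm
#'   isotropic, the acquisition resolution this pipeline targets).
#' @return An object of class `voxel_geometry`.
#' @export
voxel_geometry <- function(dims, spacing = c(2.5, 2.5, 2.5)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  if (length(dims) != 3 || any(is.na(dims)) || any(dims < 1)) {
    stop("voxel_geometry: dims must be an integer triple, all >= 1",
         call. = FALSE)
  }
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel_geometry: spacing must be a positive triple (mm)",
         call. = FALSE)
  }
  structure(list(dims = dims, spacing = spacing), class = "voxel_geometry")
}

#' Voxel volume in cubic millimetres
#' @param geometry A `voxel_geometry`.
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  prod(geometry$spacing)
}

same_grid <- function(a, b) {
  identical(a$dims, b$dims) && isTRUE(all.equal(a$spacing, b$spacing))
}

#' Multi-echo magnitude volume
#'
#' A 4D magnitude image indexed (x, y, z, echo) together with its echo times
#' and voxel geometry; the input to the T2* fit.
#'
#' @param data 4D non-negative finite array; 4th dimension length must equal
#'   the number of echo times.
#' @param echoes An [echo_times] object.
#' @param geometry A [voxel_geometry] whose dims match `dim(data)[1:3]`.
#' @return An object of class `multiecho_volume`.
#' @export
multiecho_volume <- function(data, echoes, geometry) {
  stopifnot(inherits(echoes, "echo_times"), inherits(geometry, "voxel_geometry"))
  if (length(dim(data)) != 4) {
    stop("multiecho_volume: data must be 4D (x, y, z, echo)", call. = FALSE)
  }
  if (dim(data)[4] != length(echoes)) {
    stop(sprintf(
      "multiecho_volume: 4th dimension (%d) does not match echo count (%d)",
      dim(data)[4], length(echoes)), call. = FALSE)
  }
  if (!identical(as.integer(dim(data)[1:3]), geometry$dims)) {
    stop("multiecho_volume: data grid does not match geometry dims",
         call. = FALSE)
  }
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("multiecho_volume: data must be finite and non-negative",
         call. = FALSE)
  }
  structure(list(data = data, echoes = echoes, geometry = geometry),
            class = "multiecho_volume")
}

#' Binary organ mask
#'
#' @param data 3D array coercible to 0/1 (values > 0.5 are foreground).
#' @param geometry A [voxel_geometry]; must match `dim(data)`.
#' @param label Organ label, `"placenta"` or `"brain"`.
#' @return An object of class `binary_mask`; `attr(, "empty")` is TRUE when
#'   the mask has no foreground voxel (flagged, not an error, so that a
#'   subject with a failed segmentation can be carried as invalid).
#' @export
binary_mask <- function(data, geometry, label = c("placenta", "brain")) {
  label <- match.arg(label)
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (length(dim(data)) != 3) {
    stop("binary_mask: data must be 3D", call. = FALSE)
  }
  if (!identical(as.integer(dim(data)), geometry$dims)) {
    stop("binary_mask: mask grid does not match geometry dims", call. = FALSE)
  }
  bin <- array(as.integer(data > 0.5), dim = dim(data))
  empty <- sum(bin) == 0L
  if (empty) {
    warning(sprintf("binary_mask: %s mask is empty; ROI flagged invalid",
                    label), call. = FALSE)
  }
  structure(list(data = bin, geometry = geometry, label = label),
            class = "binary_mask", empty = empty)
}

#' Is a mask empty (no foreground voxels)?
#' @param mask A `binary_mask`.
#' @return Logical.
#' @export
is_empty_mask <- function(mask) isTRUE(attr(mask, "empty"))

#' Scalar voxel map with validity flags
#'
#' Houses voxelwise fit outputs (T2* in msec, S0 in signal units) and
#' distance maps (mm). Invalid voxels carry `NA` in `data` and 0 in
#' `validity`; they are never silently zero-filled.
#'
#' @param data 3D numeric array; `NA` at invalid voxels.
#' @param geometry A [voxel_geometry].
#' @param units Unit string (`"msec"`, `"mm"`, `"signal"`).
#' @param validity Optional 3D 0/1 array of successful-fit flags; defaults to
#'   `is.finite(data)`.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(data, geometry, units, validity = NULL) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (length(dim(data)) != 3 ||
      !identical(as.integer(dim(data)), geometry$dims)) {
    stop("scalar_map: data must be 3D on the geometry grid", call. = FALSE)
  }
  if (is.null(validity)) {
    validity <- array(as.integer(is.finite(data)), dim = dim(data))
  } else {
    validity <- array(as.integer(validity > 0), dim = dim(data))
    if (!identical(dim(validity), dim(data))) {
      stop("scalar_map: validity grid mismatch", call. = FALSE)
    }
  }
  data[validity == 0L] <- NA_real_
  structure(list(data = data, geometry = geometry, units = units,
                 validity = validity),
            class = "scalar_map")
}

#' Assemble a per-subject record
#'
#' One row of the cohort table: identifiers, covariates and the six imaging
#' metrics the analysis compares between groups.
#'
#' @param id Subject identifier (unique within a cohort).
#' @param group `"control"` or `"CHD"`.
#' @param ga_weeks Gestational age at scan, weeks (must lie in (20, 45)).
#' @param maternal_age_years Maternal age at scan, years.
#' @param placenta_t2 Mean placental T2* below threshold, msec.
#' @param brain_t2 Mean fetal-brain T2* below threshold, msec.
#' @param volume_mm3 Placental volume, mm^3.
#' @param texture Placental GLCM correlation, dimensionless.
#' @param morphology Placental morphology score (mean + SD of the boundary
#'   distance map, mm-valued).
#' @param thickness_mm Maximum placental thickness estimate, mm.
#' @return A one-row data.frame.
#' @export
subject_record <- function(id, group, ga_weeks, maternal_age_years,
                           placenta_t2 = NA_real_, brain_t2 = NA_real_,
                           volume_mm3 = NA_real_, texture = NA_real_,
                           morphology = NA_real_, thickness_mm = NA_real_) {
  group <- match.arg(group, c("control", "CHD"))
  if (!is.na(ga_weeks) && (ga_weeks <= 20 || ga_weeks >= 45)) {
    stop("subject_record: ga_weeks must lie in (20, 45)", call. = FALSE)
  }
  data.frame(id = as.character(id), group = group,
             ga_weeks = as.numeric(ga_weeks),
             maternal_age_years = as.numeric(maternal_age_years),
             placenta_t2 = placenta_t2, brain_t2 = brain_t2,
             volume_mm3 = volume_mm3, texture = texture,
             morphology = morphology, thickness_mm = thickness_mm,
             stringsAsFactors = FALSE)
}

cohort_columns <- c("id", "group", "ga_weeks", "maternal_age_years",
                    "placenta_t2", "brain_t2", "volume_mm3", "texture",
                    "morphology", "thickness_mm")

#' Validate a cohort table
#'
#' @param table Data.frame with the columns of [subject_record()].
#' @param require_groups If TRUE, insist on >= 2 records per group (needed by
#'   any between-group test).
#' @return The table, invisibly, after validation.
#' @export
validate_cohort <- function(table, require_groups = FALSE) {
  missing_cols <- setdiff(cohort_columns, names(table))
  if (length(missing_cols)) {
    stop("cohort table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(table$id)) {
    stop("cohort table has duplicate subject ids", call. = FALSE)
  }
  if (!all(table$group %in% c("control", "CHD"))) {
    stop("cohort group labels must be 'control' or 'CHD'", call. = FALSE)
  }
  if (require_groups) {
    counts <- table(factor(table$group, levels = c("control", "CHD")))
    if (any(counts < 2)) {
      stop("between-group tests need >= 2 records per group", call. = FALSE)
    }
  }
  invisible(table)
}
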