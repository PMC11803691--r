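#' Read a multi-echo volume from NIfTI plus a JSON sidecar
#'
#' The sidecar is BIDS-flavoured JSON with an `"EchoTimes"` key giving the
#' echo times in msec; the echo count is cross-checked against the image's
#' 4th dimension.
#'
#' @param image_path Path to a 4D NIfTI (.nii/.nii.gz), echo as 4th dim.
#' @param sidecar_path Path to the JSON sidecar.
#' @return A [multiecho_volume].
#' @export
read_multiecho <- function(image_path, sidecar_path) {
  if (!file.exists(sidecar_path)) {
    stop("read_multiecho: sidecar not found: ", sidecar_path, call. = FALSE)
  }
  img <- RNifti::readNifti(image_path)
  d <- dim(img)
  if (length(d) != 4) {
    stop("read_multiecho: image must be 4D (x, y, z, echo); got ",
         length(d), "D", call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$EchoTimes)) {
    stop("read_multiecho: sidecar has no 'EchoTimes' key", call. = FALSE)
  }
  te <- echo_times(meta$EchoTimes)
  if (length(te) != d[4]) {
    stop(sprintf(
      "read_multiecho: sidecar lists %d echo times but image has %d echoes",
      length(te), d[4]), call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  geom <- voxel_geometry(d[1:3], spacing)
  multiecho_volume(array(as.numeric(img), dim = d), te, geom)
}

#' Write a multi-echo volume as NIfTI plus JSON sidecar
#'
#' @param volume A [multiecho_volume].
#' @param image_path Output NIfTI path.
#' @param sidecar_path Output JSON sidecar path (holds `"EchoTimes"`, msec).
#' @return `image_path`, invisibly.
#' @export
write_multiecho <- function(volume, image_path, sidecar_path) {
  stopifnot(inherits(volume, "multiecho_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- c(volume$geometry$spacing, 1)
  RNifti::writeNifti(img, image_path)
  jsonlite::write_json(list(EchoTimes = as.numeric(volume$echoes)),
                       sidecar_path, auto_unbox = FALSE, digits = NA)
  invisible(image_path)
}

#' Read a binary mask and check it against a reference grid
#'
#' @param path Path to a 3D NIfTI; values > 0.5 are foreground.
#' @param reference A [voxel_geometry] the mask must match.
#' @param label Organ label passed to [binary_mask()].
#' @return A [binary_mask]; empty masks are flagged (see [is_empty_mask()]).
#' @export
read_mask <- function(path, reference, label = c("placenta", "brain")) {
  label <- match.arg(label)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) {
    stop("read_mask: mask must be 3D", call. = FALSE)
  }
  if (!identical(as.integer(d), reference$dims)) {
    stop(sprintf("read_mask: mask grid %s does not match reference %s",
                 paste(d, collapse = "x"),
                 paste(reference$dims, collapse = "x")), call. = FALSE)
  }
  binary_mask(array(as.numeric(img), dim = d), reference, label)
}

#' Write a binary mask as unsigned 8-bit NIfTI
#' @param mask A [binary_mask].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim = dim(mask$data)))
  RNifti::pixdim(img) <- mask$geometry$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write a scalar map as NIfTI, units recorded in the header description
#'
#' Invalid voxels are written as NaN so they can never be mistaken for
#' measured zeros.
#'
#' @param map A [scalar_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scalar_map <- function(map, path) {
  stopifnot(inherits(map, "scalar_map"))
  dat <- map$data
  dat[map$validity == 0L] <- NaN
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- map$geometry$spacing
  img$descrip <- paste0("units=", map$units)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a scalar map written by [write_scalar_map()]
#' @param path NIfTI path.
#' @param units Unit string to attach; if omitted, recovered from the
#'   `units=` tag [write_scalar_map()] places in the NIfTI description
#'   (falling back to `"unknown"`).
#' @return A [scalar_map]; non-finite voxels become invalid.
#' @export
read_scalar_map <- function(path, units = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) stop("read_scalar_map: map must be 3D", call. = FALSE)
  if (is.null(units)) {
    descrip <- RNifti::niftiHeader(img)$descrip
    units <- if (grepl("^units=", descrip)) {
      sub("^units=", "", descrip)
    } else {
      "unknown"
    }
  }
  geom <- voxel_geometry(d, RNifti::pixdim(img)[1:3])
  scalar_map(array(as.numeric(img), dim = d), geom, units)
}

#' Write a cohort table to CSV
#'
#' Fixed column order: id, group, ga_weeks, maternal_age_years, placenta_t2,
#' brain_t2, volume_mm3, texture, morphology, thickness_mm. Round-trips
#' losslessly through [read_cohort_table()] up to floating-point text
#' representation (15 significant digits are written).
#'
#' @param table A cohort data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  validate_cohort(table)
  out <- table[, cohort_columns, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15,
                                                  scientific = FALSE,
                                                  trim = TRUE))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a cohort table written by [write_cohort_table()]
#' @param path CSV path.
#' @return Validated cohort data.frame.
#' @export
read_cohort_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(id = "character", group = "character"))
  validate_cohort(tab)
  tab
}

#' Read a YAML run configuration
#'
#' Recognised keys (all optional, defaults shown): `threshold_msec` (500),
#' `cap_msec` (1000), `texture` (list: `n_levels` 32, `lo_pct` 1, `hi_pct`
#' 99), `seed` (1), `output_dir`.
#'
#' @param path YAML file path.
#' @return A run-config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  run_config(cfg)
}

#' Build a run configuration from a (possibly partial) list
#' @param cfg Named list of overrides.
#' @return Full config list.
#' @export
run_config <- function(cfg = list()) {
  defaults <- list(
    threshold_msec = 500,
    cap_msec = 1000,
    texture = list(n_levels = 32L, lo_pct = 1, hi_pct = 99),
    seed = 1L,
    output_dir = NULL
  )
  out <- utils::modifyList(defaults, cfg)
  if (out$threshold_msec <= 0) {
    stop("run_config: threshold_msec must be > 0", call. = FALSE)
  }
  out
}
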