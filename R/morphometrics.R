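#' Placental volume from a binary mask
#'
#' Foreground voxel count multiplied by the voxel volume; at 2.5 mm
#' isotropic resolution each voxel contributes 15.625 mm^3.
#'
#' @param mask A [binary_mask].
#' @param geometry Optional [voxel_geometry]; defaults to the mask's own.
#' @return Volume in mm^3 (0 for an empty mask).
#' @export
mask_volume <- function(mask, geometry = mask$geometry) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * voxel_volume(geometry)
}

#' Euclidean distance-to-boundary map
#'
#' Assigns every foreground voxel its distance in millimetres (anisotropy
#' aware) to the centre of the nearest background voxel, so an isolated
#' voxel scores one spacing, never zero. Background voxels are invalid in
#' the result. This boundary-proximity map is the basis of the morphology
#' score and the thickness estimate.
#'
#' @param mask A non-empty [binary_mask].
#' @param geometry Optional [voxel_geometry]; defaults to the mask's own.
#' @return A [scalar_map] in mm, valid only on the foreground.
#' @export
distance_map <- function(mask, geometry = mask$geometry) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is_empty_mask(mask)) {
    stop("distance_map: mask is empty", call. = FALSE)
  }
  if (all(mask$data == 1L)) {
    stop("distance_map: mask has no background voxel on the grid",
         call. = FALSE)
  }
  d <- .edt3d_cpp(as.integer(mask$data), geometry$dims,
                  as.numeric(geometry$spacing))
  d <- array(d, dim = geometry$dims)
  d[mask$data == 0L] <- NA_real_
  scalar_map(d, geometry, "mm", validity = mask$data)
}

#' Placental morphology score
#'
#' Mean plus standard deviation (population, N denominator) of the boundary
#' distance map over the foreground. Higher values correspond to bulkier,
#' less uniformly shaped placentas; thin uniform discs score low.
#'
#' @param dmap A distance [scalar_map] produced by [distance_map()].
#' @param mask The [binary_mask] the map was computed from.
#' @return Dimensionless score (mm-valued distances; see package vignette on
#'   units).
#' @export
morphology_score <- function(dmap, mask) {
  stopifnot(inherits(dmap, "scalar_map"), inherits(mask, "binary_mask"))
  if (!same_grid(dmap$geometry, mask$geometry)) {
    stop("morphology_score: map and mask are on different grids",
         call. = FALSE)
  }
  vals <- dmap$data[mask$data == 1L & dmap$validity == 1L]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("morphology_score: empty mask", call. = FALSE)
  m <- mean(vals)
  sd_pop <- sqrt(mean((vals - m)^2))
  m + sd_pop
}

#' Maximum-thickness estimate
#'
#' Twice the largest value of the boundary distance map: the deepest voxel
#' sits halfway through the organ's thickest extent.
#'
#' @param dmap A distance [scalar_map].
#' @return Thickness in mm.
#' @export
max_thickness <- function(dmap) {
  stopifnot(inherits(dmap, "scalar_map"))
  vals <- dmap$data[dmap$validity == 1L]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("max_thickness: empty distance map", call. = FALSE)
  2 * max(vals)
}

#' All placental shape metrics at once
#'
#' @param mask A non-empty [binary_mask].
#' @return List with `volume_mm3`, `morphology_score`, `max_thickness_mm`
#'   and the `distance_map` itself.
#' @export
morphology_metrics <- function(mask) {
  dmap <- distance_map(mask)
  list(
    volume_mm3 = mask_volume(mask),
    morphology_score = morphology_score(dmap, mask),
    max_thickness_mm = max_thickness(dmap),
    distance_map = dmap
  )
}
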