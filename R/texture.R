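#' Quantize a scalar map for co-occurrence analysis
#'
#' Linear binning of in-mask values into `n_levels` grey levels between two
#' robust percentiles of the in-mask distribution, with clipping. Being
#' percentile based, the binning is invariant to affine rescaling of the
#' input. Out-of-mask and invalid voxels are tagged ignore (NA).
#'
#' @param map A [scalar_map].
#' @param mask A [binary_mask] on the same grid.
#' @param n_levels Number of grey levels L (default 32).
#' @param lo_pct,hi_pct Robust percentile bounds (default 1 and 99).
#' @param exclude_above Optional value; in-mask voxels at or above it are
#'   tagged ignore before binning (used to drop fluid-like T2* voxels).
#' @return 3D integer array with levels in `[0, n_levels - 1]`, NA at
#'   ignored voxels, and attribute `degenerate` TRUE when fewer than 2
#'   distinct finite values remain (co-occurrence correlation undefined).
#' @export
quantize <- function(map, mask, n_levels = 32L, lo_pct = 1, hi_pct = 99,
                     exclude_above = NULL) {
  stopifnot(inherits(map, "scalar_map"), inherits(mask, "binary_mask"))
  if (!same_grid(map$geometry, mask$geometry)) {
    stop("quantize: map and mask are on different grids", call. = FALSE)
  }
  use <- mask$data == 1L & map$validity == 1L & is.finite(map$data)
  if (!is.null(exclude_above)) {
    use <- use & map$data < exclude_above
  }
  vals <- map$data[use]
  q <- array(NA_integer_, dim = dim(map$data))
  degenerate <- length(unique(vals)) < 2
  if (!degenerate) {
    bounds <- quantile(vals, c(lo_pct, hi_pct) / 100, names = FALSE,
                       type = 7)
    lo <- bounds[1]; hi <- bounds[2]
    if (hi <= lo) {
      degenerate <- TRUE
    } else {
      lev <- floor((map$data[use] - lo) / (hi - lo) * n_levels)
      lev <- pmin(pmax(lev, 0), n_levels - 1)
      q[use] <- as.integer(lev)
    }
  }
  structure(q, degenerate = degenerate, n_levels = as.integer(n_levels))
}

default_offsets <- function() {
  list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
}

shift_index <- function(dims, d) {
  # linear indices of voxels whose displaced partner is still on the grid
  x <- seq_len(dims[1] - abs(d[1])) + max(0L, -d[1])
  y <- seq_len(dims[2] - abs(d[2])) + max(0L, -d[2])
  z <- seq_len(dims[3] - abs(d[3])) + max(0L, -d[3])
  list(x = x, y = y, z = z)
}

#' Accumulate a symmetric grey-level co-occurrence matrix
#'
#' Counts level pairs (v(p), v(p + d)) with both voxels inside the mask and
#' neither ignored, over every offset and its negation (symmetric
#' accumulation), then normalises the matrix to sum 1.
#'
#' @param q Quantized integer image from [quantize()].
#' @param mask A [binary_mask].
#' @param offsets List of nonzero integer displacement triples; default the
#'   three axis-aligned unit displacements (3D accumulation).
#' @return List of class `glcm`: `p` (L x L normalised symmetric matrix),
#'   `offsets`, `n_levels`, `n_pairs` (raw symmetric pair count).
#' @export
glcm_accumulate <- function(q, mask, offsets = default_offsets()) {
  stopifnot(inherits(mask, "binary_mask"))
  if (isTRUE(attr(q, "degenerate"))) {
    stop("glcm_accumulate: quantized image is degenerate", call. = FALSE)
  }
  L <- attr(q, "n_levels")
  dims <- dim(q)
  valid <- !is.na(q) & mask$data == 1L
  counts <- matrix(0, L, L)
  for (d in offsets) {
    d <- as.integer(d)
    if (all(d == 0L) || any(abs(d) >= dims)) {
      stop("glcm_accumulate: offset must be nonzero and within the grid",
           call. = FALSE)
    }
    s <- shift_index(dims, d)
    a <- q[s$x, s$y, s$z, drop = FALSE]
    b <- q[s$x + d[1], s$y + d[2], s$z + d[3], drop = FALSE]
    va <- valid[s$x, s$y, s$z, drop = FALSE]
    vb <- valid[s$x + d[1], s$y + d[2], s$z + d[3], drop = FALSE]
    keep <- va & vb
    if (any(keep)) {
      idx <- a[keep] * L + b[keep]  # 0-based (i, j) -> flat
      tab <- tabulate(idx + 1L, nbins = L * L)
      counts <- counts + matrix(tab, L, L, byrow = TRUE)
    }
  }
  counts <- counts + t(counts)  # count each pair in both orders
  total <- sum(counts)
  if (total == 0) {
    stop("glcm_accumulate: no valid voxel pairs", call. = FALSE)
  }
  structure(list(p = counts / total, offsets = offsets, n_levels = L,
                 n_pairs = total), class = "glcm")
}

#' GLCM correlation statistic
#'
#' Haralick correlation of the normalised symmetric co-occurrence matrix:
#' sum over (i, j) of p(i,j) (i - mu)(j - mu) / sigma^2, with mu and sigma
#' the marginal mean and SD (the two marginals coincide for a symmetric
#' matrix). Lies in [-1, 1]; lower values indicate more heterogeneous
#' tissue.
#'
#' @param g A `glcm` from [glcm_accumulate()].
#' @return Correlation in [-1, 1], or `NA` when a marginal SD is zero
#'   (constant image — undefined, not 0).
#' @export
glcm_correlation <- function(g) {
  stopifnot(inherits(g, "glcm"))
  p <- g$p
  L <- g$n_levels
  i <- seq_len(L) - 1
  pi_marg <- rowSums(p)
  mu <- sum(i * pi_marg)
  sigma2 <- sum((i - mu)^2 * pi_marg)
  if (sigma2 <= 0) return(NA_real_)
  eij <- sum(p * outer(i, i))
  (eij - mu^2) / sigma2
}

#' Placental texture
#'
#' The scalar texture metric of the pipeline: quantize the (thresholded) T2*
#' map over the placental mask, accumulate the symmetric 3D co-occurrence
#' matrix, and return its correlation. Values near 1 indicate spatially
#' smooth, homogeneous-looking tissue; lower values more heterogeneous
#' tissue.
#'
#' @param t2star A T2* [scalar_map] (or, if preferred, a first-echo
#'   magnitude map — any scalar map works).
#' @param mask Placental [binary_mask].
#' @param n_levels,lo_pct,hi_pct Quantization parameters (defaults 32, 1,
#'   99).
#' @param offsets Displacement set (default axis-aligned 3D units).
#' @param threshold Values at or above this are excluded before
#'   quantization, msec (default 500, matching the ROI mean threshold).
#' @return Texture in [-1, 1], `NA` for degenerate (e.g. constant) inputs.
#' @export
placental_texture <- function(t2star, mask, n_levels = 32L, lo_pct = 1,
                              hi_pct = 99, offsets = default_offsets(),
                              threshold = 500) {
  q <- quantize(t2star, mask, n_levels = n_levels, lo_pct = lo_pct,
                hi_pct = hi_pct, exclude_above = threshold)
  if (isTRUE(attr(q, "degenerate"))) return(NA_real_)
  g <- glcm_accumulate(q, mask, offsets = offsets)
  glcm_correlation(g)
}
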