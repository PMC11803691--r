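#' @section Model:
#' Voxelwise mono-exponential decay S(TE) = S0 * exp(-TE / T2*), fitted by
#' nonlinear least squares over all acquired echo times. The fit is
#' parameterised internally as (S0, R2* = 1/T2*) for numerical stability and
#' run simultaneously over all voxels.
#' @name relaxometry
NULL

T2_MIN_MSEC <- 0.01  # lower clamp on fitted T2*; below this a fit is absurd

# Vectorised log-linear initialiser over a signal matrix (voxels x echoes).
# OLS of log(signal) on TE using only strictly positive samples; slope is
# -1/T2*, intercept log(S0). Rows with < 2 positive samples or slope >= 0
# are flagged not converged.
loglinear_init_matrix <- function(S, te) {
  w <- (S > 0) * 1
  n <- rowSums(w)
  y <- log(pmax(S, .Machine$double.xmin)) * w
  TEm <- matrix(te, nrow = nrow(S), ncol = length(te), byrow = TRUE)
  sx <- rowSums(TEm * w)
  sy <- rowSums(y)
  sxx <- rowSums(TEm^2 * w)
  sxy <- rowSums(TEm * y)
  denom <- n * sxx - sx^2
  slope <- ifelse(denom > 0, (n * sxy - sx * sy) / denom, NA_real_)
  intercept <- ifelse(n > 0, (sy - slope * sx) / n, NA_real_)
  ok <- n >= 2 & is.finite(slope) & slope < 0
  list(s0 = exp(intercept), t2star = -1 / slope, converged = ok)
}

model_sse <- function(S, te, A, R) {
  E <- exp(-outer(R, te))
  rowSums((S - A * E)^2)
}

# Vectorised Levenberg-Marquardt refinement of (S0, R2*) for the
# mono-exponential model, over all voxels at once. Steps are accepted only
# when they reduce the per-voxel SSE, so the final SSE never exceeds that of
# the (clamped) initialiser.
fit_voxels <- function(S, te, cap = 1000, maxit = 60L) {
  n <- nrow(S)
  init <- loglinear_init_matrix(S, te)
  conv <- init$converged
  A <- ifelse(conv, pmax(init$s0, .Machine$double.xmin), NA_real_)
  Rmin <- 1 / cap
  Rmax <- 1 / T2_MIN_MSEC
  R <- ifelse(conv, pmin(pmax(1 / init$t2star, Rmin), Rmax), NA_real_)

  sse <- rep(NA_real_, n)
  idx <- which(conv)
  if (length(idx)) {
    a <- A[idx]; r <- R[idx]
    Ssub <- S[idx, , drop = FALSE]
    f <- model_sse(Ssub, te, a, r)
    lambda <- rep(1e-3, length(idx))
    active <- rep(TRUE, length(idx))
    for (it in seq_len(maxit)) {
      if (!any(active)) break
      ai <- which(active)
      aa <- a[ai]; rr <- r[ai]
      Sa <- Ssub[ai, , drop = FALSE]
      E <- exp(-outer(rr, te))
      M <- aa * E
      res <- Sa - M
      J2 <- -M * matrix(te, nrow = length(ai), ncol = length(te), byrow = TRUE)
      g11 <- rowSums(E * E)
      g12 <- rowSums(E * J2)
      g22 <- rowSums(J2 * J2)
      b1 <- rowSums(E * res)
      b2 <- rowSums(J2 * res)
      d11 <- g11 * (1 + lambda[ai])
      d22 <- g22 * (1 + lambda[ai])
      det <- d11 * d22 - g12^2
      det[det == 0 | !is.finite(det)] <- NA_real_
      dA <- (d22 * b1 - g12 * b2) / det
      dR <- (d11 * b2 - g12 * b1) / det
      a_new <- pmax(aa + dA, .Machine$double.xmin)
      r_new <- pmin(pmax(rr + dR, Rmin), Rmax)
      f_new <- model_sse(Sa, te, a_new, r_new)
      better <- is.finite(f_new) & f_new <= f[ai]
      step <- pmax(abs(dA) / pmax(aa, 1e-300), abs(dR) / pmax(rr, 1e-300))
      # accept improving steps, raise damping on the rest
      acc <- ai[better]
      a[acc] <- a_new[better]
      r[acc] <- r_new[better]
      dropped <- f[acc] - f_new[better]
      f[acc] <- f_new[better]
      lambda[acc] <- lambda[acc] / 3
      rej <- ai[!better]
      lambda[rej] <- lambda[rej] * 4
      done <- logical(length(ai))
      done[better] <- step[better] < 1e-12 |
        dropped <= 1e-14 * pmax(f_new[better], .Machine$double.xmin)
      done[!better] <- lambda[rej] > 1e12
      active[ai[done]] <- FALSE
    }
    A[idx] <- a
    R[idx] <- r
    sse[idx] <- f
  }
  list(s0 = ifelse(conv, A, NA_real_),
       t2star = ifelse(conv, 1 / R, NA_real_),
       converged = conv,
       residual_sse = sse)
}

fit_result <- function(s0, t2star, converged, residual_sse) {
  list(s0 = s0, t2star = t2star, converged = isTRUE(converged),
       residual_sse = residual_sse)
}

#' Log-linear initial estimate of (S0, T2*)
#'
#' Ordinary least squares of log(signal) against echo time; the slope is
#' -1/T2* and the intercept log(S0). Non-positive samples are excluded from
#' the log fit. Exact on noiseless decays.
#'
#' @param signal Non-negative signal vector, one value per echo.
#' @param echoes An [echo_times].
#' @return A fit-result list with fields `s0`, `t2star` (msec), `converged`
#'   and `residual_sse` (SSE of the exponential model at these parameters,
#'   over all echoes as measured). `converged` is FALSE when fewer than 2
#'   samples are positive or the slope is non-negative (non-decaying signal).
#' @export
loglinear_init <- function(signal, echoes) {
  stopifnot(inherits(echoes, "echo_times"), length(signal) == length(echoes))
  te <- as.numeric(echoes)
  init <- loglinear_init_matrix(matrix(signal, nrow = 1), te)
  if (!init$converged) {
    return(fit_result(NA_real_, NA_real_, FALSE, NA_real_))
  }
  sse <- model_sse(matrix(signal, nrow = 1), te, init$s0, 1 / init$t2star)
  fit_result(init$s0, init$t2star, TRUE, sse)
}

#' Nonlinear least-squares mono-exponential fit for one voxel
#'
#' Minimises the sum over echoes of (signal - S0 * exp(-TE/T2*))^2,
#' initialised from [loglinear_init()], with T2* constrained to (0, cap].
#' The refined SSE never exceeds the initialiser's. Voxels whose initialiser
#' fails (all-zero or non-decaying signal) are returned non-converged rather
#' than force-fitted.
#'
#' @param signal Non-negative signal vector over echoes.
#' @param echoes An [echo_times].
#' @param cap Upper T2* bound during fitting, msec (default 1000; distinct
#'   from the 500 msec reporting threshold so near-fluid voxels fit stably
#'   and are excluded later).
#' @return A fit-result list (`s0`, `t2star`, `converged`, `residual_sse`).
#' @export
fit_monoexponential <- function(signal, echoes, cap = 1000) {
  stopifnot(inherits(echoes, "echo_times"), length(signal) == length(echoes))
  te <- as.numeric(echoes)
  r <- fit_voxels(matrix(signal, nrow = 1), te, cap = cap)
  fit_result(r$s0[1], r$t2star[1], r$converged[1], r$residual_sse[1])
}

#' Voxelwise T2* and S0 maps from a multi-echo volume
#'
#' Runs the mono-exponential fit at every voxel (optionally restricted to a
#' region of interest). Non-converged voxels are invalid in the output
#' validity maps and carry NA, never a silent fill value.
#'
#' @param volume A [multiecho_volume].
#' @param roi Optional [binary_mask]; when given, only in-mask voxels are
#'   fitted and everything outside is invalid.
#' @param cap Upper T2* bound during fitting, msec.
#' @return List with `t2star` and `s0` [scalar_map]s (msec and signal units).
#' @export
fit_t2star_map <- function(volume, roi = NULL, cap = 1000) {
  stopifnot(inherits(volume, "multiecho_volume"))
  d <- dim(volume$data)
  nvox <- prod(d[1:3])
  S <- matrix(volume$data, nrow = nvox, ncol = d[4])
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "binary_mask"))
    if (!same_grid(roi$geometry, volume$geometry)) {
      stop("fit_t2star_map: roi grid does not match volume", call. = FALSE)
    }
    sel <- which(roi$data == 1L)
  } else {
    sel <- seq_len(nvox)
  }
  t2 <- rep(NA_real_, nvox)
  s0 <- rep(NA_real_, nvox)
  if (length(sel)) {
    fit <- fit_voxels(S[sel, , drop = FALSE], as.numeric(volume$echoes),
                      cap = cap)
    t2[sel] <- fit$t2star
    s0[sel] <- fit$s0
  }
  geom <- volume$geometry
  list(
    t2star = scalar_map(array(t2, dim = d[1:3]), geom, "msec"),
    s0 = scalar_map(array(s0, dim = d[1:3]), geom, "signal")
  )
}

#' Thresholded ROI mean T2*
#'
#' Arithmetic mean of T2* over voxels that are in the mask, validly fitted,
#' and strictly below the threshold. The 500 msec default excludes partial
#' voluming from amniotic fluid and CSF.
#'
#' @param t2star A T2* [scalar_map] (msec).
#' @param mask A [binary_mask] on the same grid.
#' @param threshold Exclusion threshold, msec (default 500).
#' @return Mean T2* in msec, or `NA` if no voxel qualifies.
#' @export
mean_t2star <- function(t2star, mask, threshold = 500) {
  stopifnot(inherits(t2star, "scalar_map"), inherits(mask, "binary_mask"))
  if (!same_grid(t2star$geometry, mask$geometry)) {
    stop("mean_t2star: map and mask are on different grids", call. = FALSE)
  }
  sel <- mask$data == 1L & t2star$validity == 1L &
    !is.na(t2star$data) & t2star$data < threshold
  if (!any(sel)) return(NA_real_)
  mean(t2star$data[sel])
}
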