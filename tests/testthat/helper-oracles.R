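# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive (plain loops, direct formulas) and never call the
# package's own implementation paths.

# O(n^2) nearest-background Euclidean distance, mm, anisotropy-aware.
oracle_edt <- function(mask, spacing) {
  d <- dim(mask)
  fg <- which(mask == 1L, arr.ind = TRUE)
  bg <- which(mask == 0L, arr.ind = TRUE)
  out <- array(NA_real_, dim = d)
  if (nrow(bg) == 0L) return(out)
  bgs <- sweep(bg, 2, spacing, `*`)
  for (i in seq_len(nrow(fg))) {
    p <- fg[i, ] * spacing
    dd <- sqrt(colSums((t(bgs) - p)^2))
    out[fg[i, 1], fg[i, 2], fg[i, 3]] <- min(dd)
  }
  out
}

# Direct pair enumeration for the symmetric co-occurrence matrix.
oracle_glcm <- function(q, mask, offsets, L) {
  d <- dim(q)
  counts <- matrix(0, L, L)
  for (off in offsets) {
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3])
        next
      a <- q[x, y, z]; b <- q[x2, y2, z2]
      if (is.na(a) || is.na(b)) next
      if (mask[x, y, z] != 1L || mask[x2, y2, z2] != 1L) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
      counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
    }
  }
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

# Textbook double-sum GLCM correlation.
oracle_glcm_corr <- function(p) {
  L <- nrow(p)
  i <- seq_len(L) - 1
  pi_ <- rowSums(p); pj <- colSums(p)
  mi <- sum(i * pi_); mj <- sum(i * pj)
  si <- sqrt(sum((i - mi)^2 * pi_)); sj <- sqrt(sum((i - mj)^2 * pj))
  if (si == 0 || sj == 0) return(NA_real_)
  acc <- 0
  for (a in seq_len(L)) for (b in seq_len(L)) {
    acc <- acc + p[a, b] * (a - 1 - mi) * (b - 1 - mj)
  }
  acc / (si * sj)
}

# Closed-form first-order partial correlation on midranks.
oracle_partial_rho <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Definitional O(m^2) Benjamini-Hochberg step-up adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (k in seq_len(m)) {
    i <- ord[k]
    # q(i at sorted position k) = min over j >= k of p_sorted(j) * m / j
    cand <- Inf
    for (j in k:m) {
      cand <- min(cand, p[ord[j]] * m / j)
    }
    q[i] <- min(cand, 1)
  }
  q
}

# Triple-loop in-mask thresholded mean.
oracle_mean_t2 <- function(map, valid, mask, thr) {
  d <- dim(map)
  s <- 0; n <- 0
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (mask[x, y, z] == 1L && valid[x, y, z] == 1L &&
        is.finite(map[x, y, z]) && map[x, y, z] < thr) {
      s <- s + map[x, y, z]; n <- n + 1
    }
  }
  if (n == 0) NA_real_ else s / n
}

# Exhaustive SSE grid search for the two-parameter exponential fit.
oracle_grid_fit <- function(signal, te, s0_grid, t2_grid) {
  best <- c(NA, NA); best_sse <- Inf
  for (A in s0_grid) for (T2 in t2_grid) {
    sse <- sum((signal - A * exp(-te / T2))^2)
    if (sse < best_sse) { best_sse <- sse; best <- c(A, T2) }
  }
  list(s0 = best[1], t2star = best[2], sse = best_sse)
}

# All permutations of 1..n (n small) for the exact Spearman null.
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 1
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[r:(r + nrow(sub) - 1), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# Small helper: random blobby test mask on a given grid.
random_mask <- function(dims, p = 0.4) {
  array(as.integer(runif(prod(dims)) < p), dim = dims)
}
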