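# Independent brute-force oracles used to cross-check the implementation.

# Sort-based percentile with linear interpolation between order statistics.
sortedPercentile <- function(x, p) {
  s <- sort(as.numeric(x))
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Direct triple-loop separable convolution with replicate borders.
loopConv3 <- function(a, kx = 1, ky = 1, kz = 1) {
  d <- dim(a)
  rx <- (length(kx) - 1L) / 2L
  ry <- (length(ky) - 1L) / 2L
  rz <- (length(kz) - 1L) / 2L
  out <- array(0, d)
  cl <- function(v, n) pmin(pmax(v, 1L), n)
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) for (k in seq_len(d[3L])) {
    s <- 0
    for (ti in seq_along(kx)) for (tj in seq_along(ky)) for (tk in seq_along(kz)) {
      s <- s + kx[ti] * ky[tj] * kz[tk] *
        a[cl(i + ti - rx - 1L, d[1L]), cl(j + tj - ry - 1L, d[2L]),
          cl(k + tk - rz - 1L, d[3L])]
    }
    out[i, j, k] <- s
  }
  out
}

gaussK <- function(sigma) {
  if (sigma < 1e-8) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Shift-and-add 1D convolution along one axis with replicate borders:
# an independent (pure-R, slicing-based) route for wide Gaussian kernels,
# where the tap-by-tap triple loop is too slow.
shiftConvAxis <- function(a, k, axis) {
  d <- dim(a)
  r <- (length(k) - 1L) / 2L
  out <- array(0, d)
  n <- d[axis]
  for (t in seq_along(k)) {
    idx <- pmin(pmax(seq_len(n) + (t - r - 1L), 1L), n)
    out <- out + k[t] * switch(axis,
                               a[idx, , , drop = FALSE],
                               a[, idx, , drop = FALSE],
                               a[, , idx, drop = FALSE])
  }
  out
}

shiftBlur3 <- function(a, kx, ky, kz) {
  for (ax in 1:3) {
    k <- list(kx, ky, kz)[[ax]]
    if (length(k) > 1L) a <- shiftConvAxis(a, k, ax)
  }
  a
}

# Loop-based maximum intensity projections.
loopMIPs <- function(a) {
  d <- dim(a)
  xy <- matrix(-Inf, d[1L], d[2L])
  xz <- matrix(-Inf, d[1L], d[3L])
  yz <- matrix(-Inf, d[2L], d[3L])
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) for (k in seq_len(d[3L])) {
    xy[i, j] <- max(xy[i, j], a[i, j, k])
    xz[i, k] <- max(xz[i, k], a[i, j, k])
    yz[j, k] <- max(yz[j, k], a[i, j, k])
  }
  list(xy = xy, xz = xz, yz = yz)
}

# Breadth-first flood-fill labelling (8-connected in 2D, 26 in 3D),
# raster discovery order.
floodLabel <- function(mask) {
  d <- dim(mask)
  d3 <- if (length(d) == 2L) c(d, 1L) else d
  m <- array(as.logical(mask), d3)
  lab <- array(0L, d3)
  nxt <- 0L
  for (s in which(m)) {
    if (lab[s] > 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      ind <- arrayInd(v, d3)
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        w <- ind + c(di, dj, dk)
        if (any(w < 1L) || any(w > d3)) next
        wl <- w[1L] + d3[1L] * ((w[2L] - 1L) + d3[2L] * (w[3L] - 1L))
        if (m[wl] && lab[wl] == 0L) {
          lab[wl] <- nxt
          queue <- c(queue, wl)
        }
      }
    }
  }
  array(lab, d)
}

# Dense line sampling: closest distance from target to the axis line and
# the arc position of the closest point.
lineSampleDecompose <- function(tip, target, axis, step = 0.005) {
  L <- 2 * sqrt(sum((target - tip)^2)) + 10
  ts <- seq(-L, L, by = step)
  pts <- outer(ts, axis)
  d2 <- rowSums(sweep(pts, 2L, target - tip)^2)
  i <- which.min(d2)
  list(rLateral = sqrt(d2[i]), rAxial = ts[i],
       rTotal = sqrt(sum((target - tip)^2)))
}

# Random proper rotation matrix.
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9L), 3L, 3L))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}
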