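# Image filters used by the localization pipeline. All filters replicate
# the nearest edge value at the borders and operate on ImageStack objects,
# preserving voxel geometry and channel role.

sepConvolve3 <- function(a, kx = NULL, ky = NULL, kz = NULL) {
  d <- dim(a)
  out <- as.numeric(a)
  for (ax in 0:2) {
    k <- list(kx, ky, kz)[[ax + 1L]]
    if (is.null(k) || length(k) == 1L) next
    out <- conv_axis_replicate(out, as.integer(d), as.numeric(k), ax)
  }
  array(out, dim = d)
}

gaussKernel1D <- function(sigma) {
  if (sigma < 1e-8) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq.int(-r, r), sd = sigma)
  k / sum(k)
}

withStack <- function(stack, arr) {
  initialize(stack, intensities = arr)
}

#' Percentile normalization of a substack
#'
#' Subtracts the minimum intensity, then rescales so that the 5th
#' percentile of the shifted values maps to 0 and the \code{p}-th
#' percentile maps to 1; values outside [0, 1] are clipped. If the two
#' percentiles coincide (e.g. a constant stack) the output is all zero and
#' a warning is raised, not an error.
#'
#' @param stack an \linkS4class{ImageStack} (pipette-dye channel).
#' @param p upper percentile, user-adjustable, default 98.
#' @return the normalized \linkS4class{ImageStack}, values in [0, 1].
#' @export
normalizeSubstack <- function(stack, p = 98) {
  stopifnot(is(stack, "ImageStack"))
  if (!is.finite(p) || p <= 5 || p > 100)
    paStop("p must lie in (5, 100]", "invalidParameter")
  a <- stack@intensities
  a <- a - min(a)
  q <- quantile(a, c(0.05, p / 100), names = FALSE, type = 7)
  if (q[2L] - q[1L] <= .Machine$double.eps * max(1, q[2L])) {
    warning("degenerate substack: 5th and ", p,
            "th percentiles coincide; returning all-zero image")
    return(withStack(stack, array(0, dim(a))))
  }
  a <- (a - q[1L]) / (q[2L] - q[1L])
  a[a < 0] <- 0
  a[a > 1] <- 1
  withStack(stack, a)
}

#' In-plane 3 x 3 x 1 boxcar smoothing
#'
#' Replaces each voxel by the mean of its 3 x 3 in-plane (x-y)
#' neighborhood; the kernel does not extend in z. Borders replicate the
#' nearest edge value.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @return the smoothed \linkS4class{ImageStack}.
#' @export
smoothBoxcar <- function(stack) {
  stopifnot(is(stack, "ImageStack"))
  k <- rep(1 / 3, 3L)
  withStack(stack, sepConvolve3(stack@intensities, kx = k, ky = k))
}

#' Maximum intensity projections along each dimension
#'
#' @param stack an \linkS4class{ImageStack}.
#' @return a list of three matrices: \code{xy} (nx x ny, collapsed over z),
#'   \code{xz} (nx x nz, collapsed over y) and \code{yz} (ny x nz,
#'   collapsed over x).
#' @export
maxProjections <- function(stack) {
  stopifnot(is(stack, "ImageStack"))
  a <- stack@intensities
  d <- dim(a)
  xy <- a[, , 1L, drop = TRUE]
  if (d[3L] > 1L) for (k in 2:d[3L]) xy <- pmax(xy, a[, , k])
  xz <- a[, 1L, , drop = TRUE]
  if (d[2L] > 1L) for (j in 2:d[2L]) xz <- pmax(xz, a[, j, ])
  yz <- a[1L, , , drop = TRUE]
  if (d[1L] > 1L) for (i in 2:d[1L]) yz <- pmax(yz, a[i, , ])
  list(xy = matrix(xy, d[1L], d[2L]),
       xz = matrix(xz, d[1L], d[3L]),
       yz = matrix(yz, d[2L], d[3L]))
}

#' 3D Gaussian bandpass (difference-of-Gaussians) filter
#'
#' Highlights round features between the two characteristic sizes by
#' subtracting a wide Gaussian blur from a narrow one. Sizes are given in
#' (lateral) pixels; the Gaussian sigma is half the characteristic size,
#' and the z sigma is divided by the voxel anisotropy dz/dx so the filter
#' is isotropic in microns. With the defaults (2 and 20 pixels) the
#' response peaks for blobs roughly 20 pixels across, i.e. somata of
#' radius ~5 um imaged at ~1.23 um/pixel. Output values may be negative.
#'
#' @param stack an \linkS4class{ImageStack} (cytosolic-label channel).
#' @param bandLow,bandHigh lower and upper characteristic sizes in pixels;
#'   defaults 2 and 20.
#' @return the filtered \linkS4class{ImageStack}.
#' @export
bandpass3D <- function(stack, bandLow = 2, bandHigh = 20) {
  stopifnot(is(stack, "ImageStack"))
  if (!(bandLow > 0 && bandLow < bandHigh))
    paStop("require 0 < bandLow < bandHigh", "invalidParameter")
  anis <- stack@voxelSize[3L] / stack@voxelSize[1L]
  blur <- function(size) {
    s <- size / 2
    sepConvolve3(stack@intensities,
                 kx = gaussKernel1D(s), ky = gaussKernel1D(s),
                 kz = gaussKernel1D(s / anis))
  }
  withStack(stack, blur(bandLow) - blur(bandHigh))
}
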