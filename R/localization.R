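# Automatic localization of the pipette tip and the target soma inside a
# substack.

#' Parameters for pipette tip localization
#'
#' @param p upper normalization percentile (default 98; the lower anchor is
#'   fixed at the 5th percentile).
#' @param thresholdFraction segmentation threshold as a fraction of the
#'   projection maximum (default 0.90).
#' @param minObjectPixels objects must have strictly more pixels than this
#'   to be considered (default 10).
#' @param nTipPixels number of pixels "at the tip" (extremal along the
#'   advance direction) fused into the final estimate (default 10).
#' @return a classed parameter list.
#' @export
tipLocParams <- function(p = 98, thresholdFraction = 0.90,
                         minObjectPixels = 10, nTipPixels = 10) {
  if (!(thresholdFraction > 0 && thresholdFraction <= 1))
    paStop("thresholdFraction must lie in (0, 1]", "invalidParameter")
  if (!(p > 5 && p <= 100))
    paStop("p must lie in (5, 100]", "invalidParameter")
  structure(list(p = p, thresholdFraction = thresholdFraction,
                 minObjectPixels = minObjectPixels, nTipPixels = nTipPixels),
            class = "tipLocParams")
}

#' Parameters for target soma localization
#'
#' @param bandLow,bandHigh characteristic sizes (pixels) of the Gaussian
#'   bandpass; defaults 2 and 20.
#' @param thresholdFraction fraction of the filtered-image maximum
#'   (default 0.90).
#' @param minObjectVoxels components smaller than this are eliminated
#'   (default 10; "smaller than" is strict, so 10-voxel objects survive).
#' @return a classed parameter list.
#' @export
targetLocParams <- function(bandLow = 2, bandHigh = 20,
                            thresholdFraction = 0.90, minObjectVoxels = 10) {
  if (!(bandLow > 0 && bandLow < bandHigh))
    paStop("require 0 < bandLow < bandHigh", "invalidParameter")
  if (!(thresholdFraction > 0 && thresholdFraction <= 1))
    paStop("thresholdFraction must lie in (0, 1]", "invalidParameter")
  structure(list(bandLow = bandLow, bandHigh = bandHigh,
                 thresholdFraction = thresholdFraction,
                 minObjectVoxels = minObjectVoxels),
            class = "targetLocParams")
}

# Pixels of a segmented MIP object that are extremal along the in-plane
# projection of the advance direction ("at the tip"). Returns micron
# coordinates of up to n pixels; ties broken by the second (depth-like)
# coordinate, then raster order, for determinism.
tipPixels <- function(mask, dir2, scale2, offset2, n) {
  idx <- which(mask, arr.ind = TRUE) - 1L  # 0-based
  u <- offset2[1L] + idx[, 1L] * scale2[1L]
  v <- offset2[2L] + idx[, 2L] * scale2[2L]
  if (vnorm(dir2) < 1e-12) dir2 <- c(1, 0)
  score <- u * dir2[1L] + v * dir2[2L]
  ord <- order(-score, -v, -u)
  take <- ord[seq_len(min(n, length(ord)))]
  cbind(u = u[take], v = v[take])
}

#' Locate the pipette tip in a substack
#'
#' Pipeline: percentile normalization, 3 x 3 x 1 boxcar smoothing, maximum
#' intensity projections along each dimension, threshold segmentation of
#' the largest object in each projection, selection of the
#' \code{nTipPixels} pixels at the tip (extremal along the advance
#' direction) in each projection, then fusion: z is the deepest tip pixel
#' (from the x-z and y-z projections), x the most anterior tip pixel of the
#' x-z projection, and y the average over tip pixels of the x-y projection.
#' The redundant x estimate from the x-y projection is reported in the
#' \code{"quality"} attribute as a consistency metric.
#'
#' @param substack \linkS4class{ImageStack} from the pipette-dye channel.
#' @param geometry \linkS4class{PipetteGeometry} providing the advance
#'   direction (angles only; the tip slot is ignored).
#' @param params a \code{\link{tipLocParams}} list.
#' @return micron position of the tip (length-3 numeric) with a
#'   \code{"quality"} attribute.
#' @export
locateTip <- function(substack, geometry = pipetteGeometry(),
                      params = tipLocParams()) {
  stopifnot(is(substack, "ImageStack"))
  axis <- approachAxis(geometry)
  vs <- substack@voxelSize
  o <- substack@origin
  norm <- withCallingHandlers(
    normalizeSubstack(substack, params$p),
    warning = function(w) invokeRestart("muffleWarning"))
  mips <- maxProjections(smoothBoxcar(norm))
  segs <- lapply(names(mips), function(nm) {
    s <- segmentLargest(mips[[nm]], params$thresholdFraction,
                        params$minObjectPixels)
    if (!attr(s, "found"))
      paStop(sprintf("no pipette object found in the %s projection", nm),
             "tipNotFound", projection = nm)
    s
  })
  names(segs) <- names(mips)
  n <- params$nTipPixels
  pxXY <- tipPixels(segs$xy, c(axis[1L], axis[2L]), vs[c(1L, 2L)],
                    o[c(1L, 2L)], n)
  pxXZ <- tipPixels(segs$xz, c(axis[1L], axis[3L]), vs[c(1L, 3L)],
                    o[c(1L, 3L)], n)
  pxYZ <- tipPixels(segs$yz, c(axis[2L], axis[3L]), vs[c(2L, 3L)],
                    o[c(2L, 3L)], n)
  xEst <- max(pxXZ[, "u"])                      # most anterior (x-z)
  zEst <- max(c(pxXZ[, "v"], pxYZ[, "v"]))      # deepest
  yEst <- mean(pxXY[, "v"])                     # average (x-y)
  xRedundant <- mean(pxXY[, "u"])
  est <- c(xEst, yEst, zEst)
  attr(est, "quality") <- list(
    xFromXY = xRedundant,
    xDisagreement = abs(xEst - xRedundant),
    objectSizes = vapply(segs, attr, integer(1L), "size"))
  est
}

#' Locate the target soma in a substack
#'
#' Pipeline: 3D Gaussian bandpass, threshold at
#' \code{thresholdFraction} of the filtered maximum, elimination of
#' 26-connected components smaller than \code{minObjectVoxels}, then,
#' among the survivors, the intensity-weighted center of mass (computed on
#' the filtered image clipped at zero) of the component whose center of
#' mass is closest (Euclidean, microns) to \code{nominal}. Exact ties are
#' broken by the lower component label.
#'
#' @param substack \linkS4class{ImageStack} from the cytosolic-label
#'   channel.
#' @param nominal micron position of the user-supplied nominal target.
#' @param params a \code{\link{targetLocParams}} list.
#' @return micron center-of-mass of the selected soma, with a
#'   \code{"quality"} attribute (number of candidate objects, selected
#'   label, distance to nominal).
#' @export
locateTarget <- function(substack, nominal, params = targetLocParams()) {
  stopifnot(is(substack, "ImageStack"))
  nominal <- assertPoint3(nominal, "nominal")
  f <- bandpass3D(substack, params$bandLow, params$bandHigh)@intensities
  mx <- max(f)
  if (mx <= 0)
    paStop("no suprathreshold structure in the bandpassed substack",
           "targetNotFound")
  bw <- f >= params$thresholdFraction * mx
  lab <- labelComponents(bw)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$minObjectVoxels)
  if (!length(keep))
    paStop("no candidate object survives the size filter", "targetNotFound")
  vs <- substack@voxelSize
  o <- substack@origin
  w <- pmax(f, 0)
  coms <- t(vapply(keep, function(lb) {
    vox <- which(lab == lb)
    ind <- arrayInd(vox, dim(f)) - 1L
    wt <- w[vox]
    o + colSums(ind * wt) / sum(wt) * vs
  }, numeric(3L)))
  d <- sqrt(rowSums(sweep(coms, 2L, nominal)^2))
  sel <- which.min(d)  # ties -> first, i.e. lower label
  est <- coms[sel, ]
  attr(est, "quality") <- list(nCandidates = length(keep),
                               label = keep[sel], distanceToNominal = d[sel])
  est
}
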