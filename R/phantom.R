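# Synthetic two-channel fluorescence phantoms with ground truth.
#
# The generator emulates the imaging configuration used for in vivo
# pipette guidance: ~256 x 256 x 150 stacks at (1.23, 1.23, 2) um voxels,
# a bright tapered pipette (dye-filled lumen) in one channel and
# spherical somata (radius ~5 um) over a diffuse background in the other.
# Intensities are photon counts; noise is Poisson on counts plus additive
# Gaussian read noise, applied last under a stated seed.

#' PhantomSpec: scene description for synthetic two-channel stacks
#'
#' @slot grid a \linkS4class{VoxelGrid}.
#' @slot geometry a \linkS4class{PipetteGeometry}; its tip slot is the
#'   ground-truth (undeflected) tip position.
#' @slot coneHalfAngle pipette taper half-angle in degrees (default 3).
#' @slot tipRadius apparent imaged radius of the pipette tip in microns
#'   (default 2.5): tip outer diameter of 2-3 um plus the point-spread
#'   halo visible at the low saturation level of percentile
#'   normalization.
#' @slot shankLength rendered length of the pipette shank, microns.
#' @slot pipettePeak peak pipette-channel signal above background, counts.
#' @slot cells list of cells, each \code{list(center, radius, peak)}; the
#'   first cell is the target, any others are distractors.
#' @slot backgroundLevel diffuse background, counts.
#' @slot textureLevel sd of the smooth neurite-like background texture
#'   added to the cell channel (0 = none; used by dense-labeling scenes).
#' @slot psfBlur lateral optical blur scale in microns (edge width of
#'   rendered objects); ~1 um lateral resolution is typical for in vivo
#'   two-photon imaging.
#' @slot noise list with \code{type} ("none", "gaussian", "poisson") and
#'   \code{readSigma} (Gaussian read noise sd, counts). "gaussian" adds
#'   only the detector floor; "poisson" additionally draws photon counts.
#' @slot seed integer seed for texture and noise.
#' @export
setClass("PhantomSpec",
  representation(grid = "VoxelGrid", geometry = "PipetteGeometry",
                 coneHalfAngle = "numeric", tipRadius = "numeric",
                 shankLength = "numeric", pipettePeak = "numeric",
                 cells = "list", backgroundLevel = "numeric",
                 textureLevel = "numeric", psfBlur = "numeric",
                 noise = "list", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@tipRadius <= 0 || object@coneHalfAngle <= 0)
    return("tipRadius and coneHalfAngle must be > 0")
  for (cell in object@cells) {
    if (!all(c("center", "radius", "peak") %in% names(cell)))
      return("each cell needs center, radius and peak")
    if (cell$radius <= 0) return("cell radius must be > 0")
    if (cell$peak <= object@backgroundLevel)
      return("cell peak intensity must exceed the background level")
  }
  if (!object@noise$type %in% c("none", "gaussian", "poisson"))
    return("noise type must be none, gaussian or poisson")
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults describe the reference configuration: a 256 x 256 x 150 stack
#' of (1.23, 1.23, 2) um voxels, pipette descending 31 degrees below
#' horizontal, one target soma of radius 5 um, background 25 counts and
#' peak signals 150 counts.
#'
#' @param tip ground-truth tip position, microns.
#' @param cells list of \code{list(center, radius, peak)}; default one
#'   soma of radius 5 um and peak 150 at the stack center depth.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param approachAngle,azimuth pipette orientation, degrees.
#' @param coneHalfAngle,tipRadius,shankLength,pipettePeak pipette model.
#' @param backgroundLevel,textureLevel,psfBlur,noise,seed background,
#'   optical blur and noise model; see the class documentation.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(tip = c(140, 157.4, 100),
                        cells = list(list(center = c(157.4, 157.4, 180),
                                          radius = 5, peak = 150)),
                        grid = voxelGrid(),
                        approachAngle = 31, azimuth = 0,
                        coneHalfAngle = 3, tipRadius = 2.5, shankLength = 400,
                        pipettePeak = 150, backgroundLevel = 25,
                        textureLevel = 0, psfBlur = 1,
                        noise = list(type = "poisson", readSigma = 2),
                        seed = 1L) {
  noise <- modifyList(list(type = "poisson", readSigma = 2), noise)
  new("PhantomSpec", grid = grid,
      geometry = pipetteGeometry(tip, approachAngle, azimuth),
      coneHalfAngle = as.numeric(coneHalfAngle),
      tipRadius = as.numeric(tipRadius),
      shankLength = as.numeric(shankLength),
      pipettePeak = as.numeric(pipettePeak), cells = cells,
      backgroundLevel = as.numeric(backgroundLevel),
      textureLevel = as.numeric(textureLevel),
      psfBlur = as.numeric(psfBlur), noise = noise,
      seed = as.integer(seed))
}

#' Dense-labeling variant of a phantom scene
#'
#' Adds randomly placed distractor somata and a smooth neurite-like
#' background texture to the cell channel, emulating densely labeled
#' cortex (bright somata over extensive dendritic arborization). The
#' target (first cell) is assumed to be a clearly labeled cell the
#' operator chose, so distractor peaks are drawn below the target's peak.
#'
#' @param spec a \linkS4class{PhantomSpec} whose first cell is the target.
#' @param nDistractors number of distractor somata (default 20).
#' @param zSlab half-extent in z around the target depth in which
#'   distractors are placed, microns.
#' @param peakRange,radiusRange uniform draw ranges for distractor peak
#'   and radius.
#' @param minSeparation minimum distance between the target and any
#'   distractor center, microns.
#' @param textureLevel texture sd in counts (default 4).
#' @param seed seed for distractor placement.
#' @return the modified \linkS4class{PhantomSpec}.
#' @export
densePhantomSpec <- function(spec, nDistractors = 20, zSlab = 40,
                             peakRange = c(60, 120), radiusRange = c(3.5, 5.5),
                             minSeparation = 15, textureLevel = 4,
                             seed = spec@seed) {
  target <- spec@cells[[1L]]
  ext <- (spec@grid@shape - 1L) * spec@grid@voxelSize
  cells <- list(target)
  withSeed(seed, {
    tries <- 0L
    while (length(cells) < nDistractors + 1L && tries < 50L * nDistractors) {
      tries <- tries + 1L
      ctr <- c(runif(1L, 5, ext[1L] - 5), runif(1L, 5, ext[2L] - 5),
               target$center[3L] + runif(1L, -zSlab, zSlab))
      if (vnorm(ctr - target$center) < minSeparation) next
      cells[[length(cells) + 1L]] <-
        list(center = ctr, radius = runif(1L, radiusRange[1L], radiusRange[2L]),
             peak = runif(1L, peakRange[1L], peakRange[2L]))
    }
  })
  initialize(spec, cells = cells, textureLevel = as.numeric(textureLevel))
}

# Voxel index range (0-based, clipped) covering a micron bounding box.
clipRange <- function(lo, hi, voxelSize, shape) {
  i0 <- pmax(0L, pmin(shape - 1L, as.integer(floor(lo / voxelSize)) - 1L))
  i1 <- pmax(0L, pmin(shape - 1L, as.integer(ceiling(hi / voxelSize)) + 1L))
  list(i0 = i0, i1 = i1, ok = all(i1 >= i0) && all(hi >= 0) &&
         all(lo <= (shape - 1L) * voxelSize))
}

# Add the pipette cone (solid dye-filled lumen with anti-aliased edges)
# into array `a` whose voxel (1,1,1) sits at `origin` microns.
addCone <- function(a, origin, voxelSize, tip, axis, tipRadius, halfAngle,
                    shankLength, peak, psfBlur = 1, hollow = FALSE) {
  d <- dim(a)
  tanA <- tan(halfAngle * pi / 180)
  maxR <- tipRadius + tanA * shankLength
  back <- tip - shankLength * axis
  lo <- pmin(tip, back) - maxR - 2
  hi <- pmax(tip, back) + maxR + 2
  rel <- clipRange(lo - origin, hi - origin, voxelSize, d)
  if (!rel$ok) return(a)
  ix <- rel$i0[1L]:rel$i1[1L]; iy <- rel$i0[2L]:rel$i1[2L]
  iz <- rel$i0[3L]:rel$i1[3L]
  xs <- origin[1L] + ix * voxelSize[1L]
  ys <- origin[2L] + iy * voxelSize[2L]
  zs <- origin[3L] + iz * voxelSize[3L]
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  X <- array(xs, c(nx, ny, nz))
  Y <- array(rep(ys, each = nx), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
  # s: distance behind the tip along the axis; r: radial distance
  DX <- X - tip[1L]; DY <- Y - tip[2L]; DZ <- Z - tip[3L]
  s <- -(DX * axis[1L] + DY * axis[2L] + DZ * axis[3L])
  rx <- DX + s * axis[1L]; ry <- DY + s * axis[2L]; rz <- DZ + s * axis[3L]
  r <- sqrt(rx * rx + ry * ry + rz * rz)
  edge <- max(psfBlur, 0.5 * min(voxelSize[1L], voxelSize[2L]))
  rad <- tipRadius + tanA * pmax(s, 0)
  prof <- pmin(pmax((rad - r) / edge + 0.5, 0), 1)
  if (hollow) {
    wall <- 0.35 * tipRadius
    inner <- pmin(pmax((rad - wall - r) / edge + 0.5, 0), 1)
    prof <- prof - 0.7 * inner
  }
  cap <- pmin(pmax(s / edge + 0.5, 0), 1) *
    pmin(pmax((shankLength - s) / edge + 0.5, 0), 1)
  a[ix + 1L, iy + 1L, iz + 1L] <-
    a[ix + 1L, iy + 1L, iz + 1L] + peak * prof * cap
  a
}

# Add a Gaussian-edged sphere (soma). The profile is slightly brighter at
# the center so that argmax identifies the center voxel unambiguously.
addSphere <- function(a, origin, voxelSize, center, radius, peak,
                      psfBlur = 1, warnClip = TRUE) {
  d <- dim(a)
  m <- radius + 3
  rel <- clipRange(center - m - origin, center + m - origin, voxelSize, d)
  if (!rel$ok) {
    if (warnClip)
      warning("cell at (", paste(round(center, 1), collapse = ", "),
              ") lies outside the grid; clipped")
    return(a)
  }
  ix <- rel$i0[1L]:rel$i1[1L]; iy <- rel$i0[2L]:rel$i1[2L]
  iz <- rel$i0[3L]:rel$i1[3L]
  xs <- origin[1L] + ix * voxelSize[1L] - center[1L]
  ys <- origin[2L] + iy * voxelSize[2L] - center[2L]
  zs <- origin[3L] + iz * voxelSize[3L] - center[3L]
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  r2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  r <- sqrt(r2)
  sigmaE <- 0.5 * psfBlur
  core <- 1 - 0.05 * pmin(r / radius, 1)^2
  prof <- peak * core * pnorm((radius - r) / sigmaE)
  a[ix + 1L, iy + 1L, iz + 1L] <- a[ix + 1L, iy + 1L, iz + 1L] + prof
  a
}

#' Render a two-channel phantom stack with ground truth
#'
#' The pipette channel contains the (possibly deflected) tapered pipette;
#' the cell channel contains all somata (possibly displaced) over diffuse
#' background, plus optional neurite-like texture. Noise is applied last
#' under \code{seed}, so identical seeds give bit-identical stacks.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param deflection lateral tip deflection applied to the ground-truth
#'   tip, microns.
#' @param cellShift displacement applied to every cell center, microns.
#' @param region optional \code{list(center, halfExtent)} in microns to
#'   render only a substack (the returned stacks carry the corresponding
#'   origin).
#' @param seed noise seed; defaults to \code{spec@seed}.
#' @return a list with \code{pipette} and \code{cells}
#'   (\linkS4class{ImageStack}s) and \code{truth} (tip and cell centers
#'   actually rendered, plus the applied deflection and shift).
#' @export
renderStack <- function(spec, deflection = c(0, 0, 0),
                        cellShift = c(0, 0, 0), region = NULL,
                        seed = spec@seed) {
  stopifnot(is(spec, "PhantomSpec"))
  vs <- spec@grid@voxelSize
  shape <- spec@grid@shape
  if (!is.null(region)) {
    ctr <- assertPoint3(region$center, "region center")
    he <- assertPoint3(region$halfExtent, "region halfExtent")
    i0 <- pmax(0L, as.integer(floor((ctr - he) / vs)))
    i1 <- pmin(shape - 1L, as.integer(ceiling((ctr + he) / vs)))
    if (any(i1 < i0))
      paStop("region lies outside the grid", "invalidParameter")
  } else {
    i0 <- c(0L, 0L, 0L); i1 <- shape - 1L
  }
  origin <- i0 * vs
  d <- i1 - i0 + 1L
  tip <- tipPosition(spec@geometry) + assertPoint3(deflection, "deflection")
  axis <- approachAxis(spec@geometry)
  pip <- array(spec@backgroundLevel, d)
  pip <- addCone(pip, origin, vs, tip, axis, spec@tipRadius,
                 spec@coneHalfAngle, spec@shankLength, spec@pipettePeak,
                 psfBlur = spec@psfBlur)
  cel <- array(spec@backgroundLevel, d)
  centers <- lapply(spec@cells, function(cell) cell$center + cellShift)
  for (i in seq_along(spec@cells))
    cel <- addSphere(cel, origin, vs, centers[[i]], spec@cells[[i]]$radius,
                     spec@cells[[i]]$peak - spec@backgroundLevel,
                     psfBlur = spec@psfBlur, warnClip = is.null(region))
  withSeed(seed, {
    if (spec@textureLevel > 0) {
      tex <- array(rnorm(prod(d)), d)
      tex <- sepConvolve3(tex, gaussKernel1D(1.5), gaussKernel1D(1.5),
                          gaussKernel1D(1.5 * vs[1L] / vs[3L]))
      tex <- tex / sd(tex) * spec@textureLevel
      cel <- pmax(cel + tex, 0)
    }
    applyNoise <- function(a) {
      n <- spec@noise
      if (n$type == "poisson") a[] <- rpois(length(a), lambda = pmax(a, 0))
      if (n$type %in% c("poisson", "gaussian") && n$readSigma > 0)
        a[] <- pmax(a + rnorm(length(a), sd = n$readSigma), 0)
      a
    }
    pip <- applyNoise(pip)
    cel <- applyNoise(cel)
  })
  list(pipette = imageStack(pip, vs, origin, "pipette_dye"),
       cells = imageStack(cel, vs, origin, "cytosolic_label"),
       truth = list(tip = tip, cells = centers,
                    deflection = as.numeric(deflection),
                    cellShift = as.numeric(cellShift), seed = seed))
}
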