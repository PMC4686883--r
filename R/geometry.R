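# Pipette-axis geometry and the lateral/axial separation decomposition.

#' @include AllClasses.R
NULL

#' Unit approach axis from approach angle and azimuth
#'
#' The pipette advances horizontally along the azimuth direction while
#' descending \code{approachAngle} degrees below horizontal, so the vertical
#' (z, depth) component of the axis equals \code{sin(approachAngle)}.
#'
#' @param approachAngle degrees below horizontal, strictly between -90
#'   and 90. The reference configuration mounts the pipette 31 degrees down
#'   from horizontal.
#' @param azimuth degrees in the x-y plane; 0 points anterior (+x).
#' @return unit 3-vector (x, y, z).
#' @examples
#' axisFromAngles(0, 0)    # horizontal pipette pointing +x
#' axisFromAngles(31, 0)   # (cos 31, 0, sin 31)
#' @export
axisFromAngles <- function(approachAngle, azimuth = 0) {
  if (!is.finite(approachAngle) || approachAngle <= -90 || approachAngle >= 90)
    paStop("approachAngle must lie strictly between -90 and 90 degrees",
           "invalidParameter")
  if (!is.finite(azimuth))
    paStop("azimuth must be finite", "invalidParameter")
  th <- approachAngle * pi / 180
  ph <- azimuth * pi / 180
  v <- c(cos(th) * cos(ph), cos(th) * sin(ph), sin(th))
  v / vnorm(v)
}

#' Decompose the tip-to-target separation into lateral and axial components
#'
#' \code{rAxial} is the signed projection of (target - tip) onto the axis
#' (positive when the target lies ahead of the tip along the advance
#' direction); \code{rLateral} is the distance from the target to the
#' pipette axis line; \code{rTotal} the Euclidean separation. Reporting
#' layers conventionally take \code{abs(rAxial)}.
#'
#' @param tip,target micron positions.
#' @param axis unit approach axis (checked to 1e-6).
#' @return a \linkS4class{SeparationMetrics}.
#' @examples
#' a <- axisFromAngles(31, 0)
#' tip <- c(100, 100, 150)
#' decomposeSeparation(tip, tip + 6.2 * a + 2.5 * lateralBasis(a)[1, ], a)
#' @export
decomposeSeparation <- function(tip, target, axis) {
  tip <- assertPoint3(tip, "tip")
  target <- assertPoint3(target, "target")
  axis <- assertUnitAxis(axis)
  d <- target - tip
  rAx <- sum(d * axis)
  lat <- d - rAx * axis
  new("SeparationMetrics", rLateral = vnorm(lat), rAxial = rAx,
      rTotal = vnorm(d))
}

resolveGrid <- function(grid) {
  if (is(grid, "ImageStack"))
    list(voxelSize = grid@voxelSize, origin = grid@origin,
         shape = dim(grid@intensities))
  else if (is(grid, "VoxelGrid"))
    list(voxelSize = grid@voxelSize, origin = c(0, 0, 0), shape = grid@shape)
  else if (is.numeric(grid) && length(grid) == 3L)
    list(voxelSize = as.numeric(grid), origin = c(0, 0, 0), shape = NULL)
  else paStop("grid must be a VoxelGrid, an ImageStack or a voxel-size triple",
              "invalidParameter")
}

#' Convert 0-based voxel indices to microns, and back
#'
#' Voxel centers sit at \code{origin + index * voxelSize}. The inverse
#' flags points outside the grid via the \code{"inBounds"} attribute
#' rather than raising an error.
#'
#' @param index numeric triple (or n x 3 matrix) of 0-based voxel indices.
#' @param grid a \linkS4class{VoxelGrid}, an \linkS4class{ImageStack}
#'   (whose origin is honored) or a voxel-size triple.
#' @return micron point(s); for \code{micronToVoxel}, fractional 0-based
#'   voxel indices with attribute \code{inBounds}.
#' @export
voxelToMicron <- function(index, grid) {
  g <- resolveGrid(grid)
  if (is.matrix(index))
    sweep(sweep(index, 2L, g$voxelSize, `*`), 2L, g$origin, `+`)
  else g$origin + as.numeric(index) * g$voxelSize
}

#' @rdname voxelToMicron
#' @param point micron position (or n x 3 matrix).
#' @export
micronToVoxel <- function(point, grid) {
  g <- resolveGrid(grid)
  idx <- if (is.matrix(point))
    sweep(sweep(point, 2L, g$origin, `-`), 2L, g$voxelSize, `/`)
  else (as.numeric(point) - g$origin) / g$voxelSize
  if (!is.null(g$shape)) {
    inb <- if (is.matrix(idx))
      apply(idx, 1L, function(r) all(r >= -0.5 & r <= g$shape - 0.5))
    else all(idx >= -0.5 & idx <= g$shape - 0.5)
    attr(idx, "inBounds") <- inb
  }
  idx
}
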