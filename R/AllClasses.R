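# Core S4 classes. Positions are microns in one right-handed stack frame
# (x anterior, z increasing with depth); voxel indices are 0-based and map
# to microns as origin + index * voxelSize.

#' @include AllGenerics.R utils.R
NULL

#' VoxelGrid: stack dimensions and per-axis voxel size
#'
#' @slot shape integer triple (nx, ny, nz), all >= 1.
#' @slot voxelSize micron triple (dx, dy, dz), all > 0. The configuration
#'   used throughout the examples is 256 x 256 x 150 voxels of
#'   (1.23, 1.23, 2) microns, typical for two-photon z stacks acquired for
#'   pipette guidance.
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", voxelSize = "numeric"))

setValidity("VoxelGrid", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be three integers >= 1")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be three positive finite microns")
  TRUE
})

#' Construct a VoxelGrid
#'
#' @param shape integer triple (nx, ny, nz).
#' @param voxelSize micron triple (dx, dy, dz).
#' @return a \linkS4class{VoxelGrid}.
#' @examples
#' voxelGrid(c(256, 256, 150), c(1.23, 1.23, 2))
#' @export
voxelGrid <- function(shape = c(256L, 256L, 150L),
                      voxelSize = c(1.23, 1.23, 2)) {
  new("VoxelGrid", shape = as.integer(shape), voxelSize = as.numeric(voxelSize))
}

#' ImageStack: a 3D intensity volume with voxel geometry and channel role
#'
#' Raw acquisitions are non-negative; filtered stacks (e.g. the output of
#' \code{\link{bandpass3D}}) may legitimately contain negative values, so
#' the class only enforces finiteness.
#'
#' @slot intensities 3D numeric array (nx, ny, nz).
#' @slot voxelSize micron triple.
#' @slot origin micron position of voxel (0, 0, 0); nonzero for substacks
#'   cropped out of a larger acquisition.
#' @slot channelRole one of "pipette_dye", "cytosolic_label", "unknown".
#' @export
setClass("ImageStack",
  representation(intensities = "array", voxelSize = "numeric",
                 origin = "numeric", channelRole = "character"))

setValidity("ImageStack", function(object) {
  d <- dim(object@intensities)
  if (length(d) != 3L) return("intensities must be a 3D array")
  if (anyNA(object@intensities) || any(is.infinite(object@intensities)))
    return("intensities must be finite")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive microns")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be a finite micron triple")
  if (!object@channelRole %in% c("pipette_dye", "cytosolic_label", "unknown"))
    return("channelRole must be pipette_dye, cytosolic_label or unknown")
  TRUE
})

#' Construct an ImageStack
#'
#' @param intensities 3D numeric array.
#' @param voxelSize micron triple (dx, dy, dz).
#' @param origin micron position of voxel (0,0,0) in the global frame.
#' @param channelRole channel semantics: the pipette is imaged through a dye
#'   in its internal solution ("pipette_dye"), target cells through a
#'   cytosolic fluorophore ("cytosolic_label").
#' @return an \linkS4class{ImageStack}.
#' @export
imageStack <- function(intensities, voxelSize = c(1.23, 1.23, 2),
                       origin = c(0, 0, 0), channelRole = "unknown") {
  if (is.matrix(intensities)) dim(intensities) <- c(dim(intensities), 1L)
  new("ImageStack", intensities = intensities,
      voxelSize = as.numeric(voxelSize), origin = as.numeric(origin),
      channelRole = channelRole)
}

#' @rdname pipetteAim-generics
#' @export
setMethod("intensities", "ImageStack", function(x) x@intensities)
#' @rdname pipetteAim-generics
#' @export
setMethod("voxelSize", "ImageStack", function(x) x@voxelSize)
#' @rdname pipetteAim-generics
#' @export
setMethod("voxelSize", "VoxelGrid", function(x) x@voxelSize)
#' @rdname pipetteAim-generics
#' @export
setMethod("stackOrigin", "ImageStack", function(x) x@origin)
#' @rdname pipetteAim-generics
#' @export
setMethod("channelRole", "ImageStack", function(x) x@channelRole)
#' @rdname pipetteAim-generics
#' @export
setMethod("gridShape", "ImageStack", function(x) dim(x@intensities))
#' @rdname pipetteAim-generics
#' @export
setMethod("gridShape", "VoxelGrid", function(x) x@shape)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("ImageStack [%s]: %d x %d x %d voxels of (%g, %g, %g) um\n",
              object@channelRole, d[1L], d[2L], d[3L],
              object@voxelSize[1L], object@voxelSize[2L], object@voxelSize[3L]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) um, intensity range [%.3g, %.3g]\n",
              object@origin[1L], object@origin[2L], object@origin[3L],
              min(object@intensities), max(object@intensities)))
})

#' PipetteGeometry: tip position and approach axis
#'
#' The pipette advances anterior (+x, rotated by \code{azimuth} in-plane)
#' and downward (+z), tilted \code{approachAngle} degrees below horizontal.
#' The unit approach axis is derived, see \code{\link{approachAxis}}.
#'
#' @slot tip micron position of the tip.
#' @slot approachAngle degrees below horizontal, in (-90, 90); 31 degrees
#'   in the reference configuration.
#' @slot azimuth degrees in the x-y plane (0 = +x).
#' @export
setClass("PipetteGeometry",
  representation(tip = "numeric", approachAngle = "numeric",
                 azimuth = "numeric"))

setValidity("PipetteGeometry", function(object) {
  if (length(object@tip) != 3L || any(!is.finite(object@tip)))
    return("tip must be a finite micron triple")
  if (length(object@approachAngle) != 1L || !is.finite(object@approachAngle) ||
      object@approachAngle <= -90 || object@approachAngle >= 90)
    return("approachAngle must lie strictly between -90 and 90 degrees")
  if (length(object@azimuth) != 1L || !is.finite(object@azimuth))
    return("azimuth must be a finite scalar")
  TRUE
})

#' Construct a PipetteGeometry
#'
#' @param tip micron position of the pipette tip.
#' @param approachAngle degrees below horizontal (default 31).
#' @param azimuth degrees in the x-y plane (default 0, advancing +x).
#' @return a \linkS4class{PipetteGeometry}.
#' @export
pipetteGeometry <- function(tip = c(0, 0, 0), approachAngle = 31, azimuth = 0) {
  new("PipetteGeometry", tip = assertPoint3(tip, "tip"),
      approachAngle = as.numeric(approachAngle), azimuth = as.numeric(azimuth))
}

#' @rdname pipetteAim-generics
#' @export
setMethod("tipPosition", "PipetteGeometry", function(x) x@tip)
#' @rdname pipetteAim-generics
#' @export
setMethod("approachAxis", "PipetteGeometry",
          function(x) axisFromAngles(x@approachAngle, x@azimuth))

setMethod("show", "PipetteGeometry", function(object) {
  a <- approachAxis(object)
  cat(sprintf(
    "PipetteGeometry: tip (%.2f, %.2f, %.2f) um, %g deg below horizontal, azimuth %g deg\n",
    object@tip[1L], object@tip[2L], object@tip[3L],
    object@approachAngle, object@azimuth))
  cat(sprintf("  axis (%.4f, %.4f, %.4f)\n", a[1L], a[2L], a[3L]))
})

#' SeparationMetrics: lateral/axial decomposition of tip-to-target distance
#'
#' \code{rLateral} is the closest distance from the target to the pipette
#' axis; \code{rAxial} is the signed distance along the axis from the tip to
#' the target's perpendicular foot point (positive when the target lies
#' ahead of the tip); \code{rTotal} the Euclidean tip-to-target distance.
#' The Pythagorean identity rTotal^2 = rLateral^2 + rAxial^2 is enforced.
#'
#' @slot rLateral,rAxial,rTotal microns.
#' @export
setClass("SeparationMetrics",
  representation(rLateral = "numeric", rAxial = "numeric", rTotal = "numeric"))

setValidity("SeparationMetrics", function(object) {
  if (object@rLateral < 0) return("rLateral must be >= 0")
  lhs <- object@rTotal^2
  rhs <- object@rLateral^2 + object@rAxial^2
  if (abs(lhs - rhs) > 1e-9 * max(1, lhs))
    return("rTotal^2 must equal rLateral^2 + rAxial^2")
  TRUE
})

#' @rdname pipetteAim-generics
#' @export
setMethod("rLateral", "SeparationMetrics", function(x) x@rLateral)
#' @rdname pipetteAim-generics
#' @export
setMethod("rAxial", "SeparationMetrics", function(x) x@rAxial)
#' @rdname pipetteAim-generics
#' @export
setMethod("rTotal", "SeparationMetrics", function(x) x@rTotal)

setMethod("show", "SeparationMetrics", function(object) {
  cat(sprintf(
    "SeparationMetrics: r_lateral = %.2f um, r_axial = %.2f um, r_total = %.2f um\n",
    object@rLateral, object@rAxial, object@rTotal))
})

#' ApproachPlan: ordered manipulator waypoints with phase labels
#'
#' Phases are "retract" (up and away from the brain surface along the
#' negative pipette axis), "translate" (horizontal move onto the approach
#' line), "approach" (axial steps towards the termination point) and
#' "correct" (the lateral shift introduced by \code{\link{adaptTrajectory}}).
#'
#' @slot waypoints n x 3 matrix of micron positions, in execution order.
#' @slot phase character vector, one label per waypoint.
#' @slot entryPoint micron point where the approach line crosses the pia.
#' @slot termination final waypoint, at the buffer distance R from target.
#' @slot target targeted cell center (microns).
#' @slot piaZ depth of the pia entry plane (microns).
#' @slot axis unit approach axis.
#' @slot params the \code{\link{approachParams}} list used for planning.
#' @export
setClass("ApproachPlan",
  representation(waypoints = "matrix", phase = "character",
                 entryPoint = "numeric", termination = "numeric",
                 target = "numeric", piaZ = "numeric", axis = "numeric",
                 params = "list"))

setValidity("ApproachPlan", function(object) {
  wp <- object@waypoints
  if (ncol(wp) != 3L) return("waypoints must be an n x 3 matrix")
  if (length(object@phase) != nrow(wp))
    return("one phase label per waypoint required")
  bad <- setdiff(unique(object@phase),
                 c("retract", "translate", "approach", "correct"))
  if (length(bad))
    return(paste("unknown phase label:", paste(bad, collapse = ", ")))
  axis <- object@axis
  if (abs(vnorm(axis) - 1) > 1e-6) return("axis must be unit norm")
  # Validate the final approach run (after the last non-approach waypoint):
  # collinear with the axis through the termination point, steps <= stepSize.
  idx <- which(object@phase == "approach")
  if (length(idx)) {
    nonap <- which(object@phase != "approach")
    run <- idx[idx > max(c(0L, nonap))]
    if (length(run)) {
      step <- object@params$stepSize
      prev <- if (min(run) > 1L) wp[min(run) - 1L, ] else NULL
      for (i in run) {
        d <- wp[i, ] - object@termination
        lat <- d - sum(d * axis) * axis
        if (vnorm(lat) > 1e-6)
          return("approach waypoints must lie on the axial line to termination")
        if (!is.null(prev) && vnorm(wp[i, ] - prev) > step + 1e-9)
          return("approach step exceeds stepSize")
        prev <- wp[i, ]
      }
    }
  }
  TRUE
})

#' @rdname pipetteAim-generics
#' @export
setMethod("waypoints", "ApproachPlan", function(x) x@waypoints)
#' @rdname pipetteAim-generics
#' @export
setMethod("phases", "ApproachPlan", function(x) x@phase)
#' @rdname pipetteAim-generics
#' @export
setMethod("approachAxis", "ApproachPlan", function(x) x@axis)

setMethod("show", "ApproachPlan", function(object) {
  cat(sprintf("ApproachPlan: %d waypoints (%s)\n", nrow(object@waypoints),
              paste(sprintf("%s: %d", names(table(object@phase)),
                            as.integer(table(object@phase))), collapse = ", ")))
  cat(sprintf("  entry (%.1f, %.1f, %.1f) um at pia z = %.1f um\n",
              object@entryPoint[1L], object@entryPoint[2L],
              object@entryPoint[3L], object@piaZ))
  cat(sprintf("  termination (%.1f, %.1f, %.1f) um, buffer distance R = %g um, step %g um\n",
              object@termination[1L], object@termination[2L],
              object@termination[3L], object@params$bufferDistance,
              object@params$stepSize))
})

#' AdaptiveCorrection: measured offsets driving the trajectory update
#'
#' @slot tipOffset measured minus expected tip position (microns).
#' @slot tipLateralOffset component of tipOffset perpendicular to the axis;
#'   orthogonality to the axis is enforced to 1e-9.
#' @slot targetDisplacement measured minus original target position.
#' @slot axis unit approach axis the decomposition refers to.
#' @export
setClass("AdaptiveCorrection",
  representation(tipOffset = "numeric", tipLateralOffset = "numeric",
                 targetDisplacement = "numeric", axis = "numeric"))

setValidity("AdaptiveCorrection", function(object) {
  if (abs(vnorm(object@axis) - 1) > 1e-6) return("axis must be unit norm")
  dot <- sum(object@tipLateralOffset * object@axis)
  if (abs(dot) > 1e-9 * max(1, vnorm(object@tipLateralOffset)))
    return("tipLateralOffset must be perpendicular to the axis")
  TRUE
})

setMethod("show", "AdaptiveCorrection", function(object) {
  cat(sprintf(
    "AdaptiveCorrection: |tip offset| = %.2f um (lateral %.2f), |target displacement| = %.2f um\n",
    vnorm(object@tipOffset), vnorm(object@tipLateralOffset),
    vnorm(object@targetDisplacement)))
})

#' DeflectionModel: simulated pipette bending and target drift
#'
#' Lateral deflection of the tip ramps linearly with insertion depth and
#' saturates at \code{saturationDepth} below the pia (entry-dominated
#' bending); the target drift is applied as a step once the pipette has
#' entered the tissue. Zero insertion implies zero deflection and drift.
#'
#' @slot lateral full-depth lateral deflection vector (microns).
#' @slot targetDrift displacement applied to cell centers once the pipette
#'   is in the tissue (microns).
#' @slot saturationDepth depth (microns below the pia) at which the lateral
#'   deflection reaches its full value; default 50.
#' @export
setClass("DeflectionModel",
  representation(lateral = "numeric", targetDrift = "numeric",
                 saturationDepth = "numeric"))

setValidity("DeflectionModel", function(object) {
  if (length(object@lateral) != 3L || length(object@targetDrift) != 3L)
    return("lateral and targetDrift must be micron triples")
  if (object@saturationDepth <= 0)
    return("saturationDepth must be > 0")
  TRUE
})

#' Construct a DeflectionModel
#'
#' @param lateral full-depth lateral deflection vector in microns.
#' @param targetDrift target-cell displacement vector in microns.
#' @param saturationDepth depth below the pia at which deflection saturates.
#' @return a \linkS4class{DeflectionModel}.
#' @export
deflectionModel <- function(lateral = c(0, 0, 0), targetDrift = c(0, 0, 0),
                            saturationDepth = 50) {
  new("DeflectionModel", lateral = assertPoint3(lateral, "lateral"),
      targetDrift = assertPoint3(targetDrift, "targetDrift"),
      saturationDepth = as.numeric(saturationDepth))
}

#' Deflection and drift at a given insertion depth
#'
#' @param model a \linkS4class{DeflectionModel}.
#' @param depth insertion depth below the pia in microns (<= 0 means the
#'   pipette has not entered the tissue).
#' @return \code{deflectionAt}: the lateral tip deflection vector;
#'   \code{targetDriftAt}: the cell displacement vector.
#' @export
deflectionAt <- function(model, depth) {
  if (depth <= 0) return(c(0, 0, 0))
  model@lateral * min(1, depth / model@saturationDepth)
}

#' @rdname deflectionAt
#' @export
targetDriftAt <- function(model, depth) {
  if (depth <= 0) return(c(0, 0, 0))
  model@targetDrift
}
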