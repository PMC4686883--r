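# Approach trajectory planning and adaptive mid-course correction.

#' Approach parameters
#'
#' @param bufferDistance R, the stopping distance between the tip and the
#'   target cell center along the pipette axis, in microns. Default 12
#'   (10-12 is the usual working range).
#' @param stepSize axial step length within the cortex, microns; default 3
#'   (2-4 typical). Must satisfy 0 < stepSize <= bufferDistance.
#' @param retractionClearance clearance above the pia for the retraction
#'   phase, microns; default 50.
#' @param adaptiveFraction fraction of the intracortical path depth at
#'   which the adaptive re-imaging step is taken; default 0.5 (an
#'   intermediate point along the route).
#' @return a classed parameter list.
#' @export
approachParams <- function(bufferDistance = 12, stepSize = 3,
                           retractionClearance = 50, adaptiveFraction = 0.5) {
  if (!(bufferDistance > 0))
    paStop("bufferDistance must be > 0", "invalidParameter")
  if (!(stepSize > 0 && stepSize <= bufferDistance))
    paStop("require 0 < stepSize <= bufferDistance", "invalidParameter")
  if (!(adaptiveFraction > 0 && adaptiveFraction < 1))
    paStop("adaptiveFraction must lie in (0, 1)", "invalidParameter")
  structure(list(bufferDistance = bufferDistance, stepSize = stepSize,
                 retractionClearance = retractionClearance,
                 adaptiveFraction = adaptiveFraction),
            class = "approachParams")
}

# Equally spaced axial waypoints from `from` (exclusive) to `to`
# (inclusive), each step <= stepSize.
discretizeAxial <- function(from, to, stepSize) {
  L <- vnorm(to - from)
  n <- max(1L, as.integer(ceiling(L / stepSize - 1e-12)))
  t(vapply(seq_len(n), function(k) from + (to - from) * k / n, numeric(3L)))
}

#' Plan the approach trajectory
#'
#' The plan consists of a retraction step up and away from the brain
#' surface (along the negative pipette axis until
#' \code{retractionClearance} microns above the pia), a horizontal
#' translation onto the entry line (the line parallel to the pipette axis
#' that intersects the target cell), and discrete axial steps of at most
#' \code{stepSize} microns terminating at the buffer distance R from the
#' target along the axis. All motion below the pia is purely axial.
#'
#' @param tip current micron position of the pipette tip (above the pia).
#' @param target micron position of the target cell center (below the pia).
#' @param piaZ depth of the pia entry plane, microns.
#' @param geometry a \linkS4class{PipetteGeometry} (angles are used).
#' @param params an \code{\link{approachParams}} list.
#' @return an \linkS4class{ApproachPlan}.
#' @export
planTrajectory <- function(tip, target, piaZ, geometry = pipetteGeometry(),
                           params = approachParams()) {
  tip <- assertPoint3(tip, "tip")
  target <- assertPoint3(target, "target")
  axis <- approachAxis(geometry)
  if (abs(axis[3L]) < 1e-9)
    paStop("pipette axis is parallel to the pia plane: no entry point",
           "noIntersection")
  if (!(tip[3L] < piaZ))
    paStop("tip must start above the pia (tip z < piaZ)", "invalidParameter")
  if (!(target[3L] > piaZ))
    paStop("target must lie below the pia (target z > piaZ)",
           "invalidParameter")
  R <- params$bufferDistance
  entry <- target - (target[3L] - piaZ) / axis[3L] * axis
  termination <- target - R * axis
  if (termination[3L] < piaZ) {
    warning("target lies shallower than the buffer distance below the pia; ",
            "clamping termination to the pia entry point")
    termination <- entry
  }
  wp <- NULL
  ph <- character(0L)
  clearZ <- piaZ - params$retractionClearance
  p1 <- tip
  if (tip[3L] > clearZ) {
    p1 <- tip - (tip[3L] - clearZ) / axis[3L] * axis
    wp <- rbind(wp, p1)
    ph <- c(ph, "retract")
  }
  # horizontal move onto the approach line at the current height
  q <- target - (target[3L] - p1[3L]) / axis[3L] * axis
  wp <- rbind(wp, q)
  ph <- c(ph, "translate")
  steps <- discretizeAxial(q, termination, params$stepSize)
  wp <- rbind(wp, steps)
  ph <- c(ph, rep("approach", nrow(steps)))
  dimnames(wp) <- NULL
  new("ApproachPlan", waypoints = wp, phase = ph, entryPoint = entry,
      termination = termination, target = target, piaZ = as.numeric(piaZ),
      axis = axis, params = unclass(params))
}

#' Compute the adaptive correction from re-localized tip and target
#'
#' The tip offset is measured minus expected tip; only its lateral
#' component (perpendicular to the axis) is compensated. The target
#' displacement is measured minus original target and is compensated in
#' full by translating the remaining approach path.
#'
#' @param expectedTip commanded tip position at the pause point, microns.
#' @param measuredTip re-localized tip position, microns.
#' @param originalTarget nominal target position used for planning.
#' @param measuredTarget re-localized target position.
#' @param axis unit approach axis.
#' @return an \linkS4class{AdaptiveCorrection}.
#' @export
computeCorrection <- function(expectedTip, measuredTip, originalTarget,
                              measuredTarget, axis) {
  axis <- assertUnitAxis(axis)
  off <- assertPoint3(measuredTip, "measuredTip") -
    assertPoint3(expectedTip, "expectedTip")
  lat <- off - sum(off * axis) * axis
  lat <- lat - sum(lat * axis) * axis  # second projection for exactness
  disp <- assertPoint3(measuredTarget, "measuredTarget") -
    assertPoint3(originalTarget, "originalTarget")
  new("AdaptiveCorrection", tipOffset = off, tipLateralOffset = lat,
      targetDisplacement = disp, axis = axis)
}

#' Adapt the remaining trajectory
#'
#' Shifts the remaining approach path by minus the lateral tip offset
#' (re-centering the physical tip on the planned line) and then translates
#' it by the measured target displacement; the remaining path is
#' re-discretized into axial steps of at most \code{stepSize}. Executed
#' waypoints up to \code{currentIndex} are kept; the lateral shift is
#' emitted as a waypoint with phase label \code{"correct"}. The axial
#' component of the tip offset is deliberately not compensated; the
#' termination criterion remains distance R from the (displaced) target.
#'
#' @param plan the \linkS4class{ApproachPlan} being executed.
#' @param correction an \linkS4class{AdaptiveCorrection} computed with the
#'   same axis as \code{plan}.
#' @param currentIndex index of the last executed waypoint (the pause
#'   point).
#' @return the updated \linkS4class{ApproachPlan}.
#' @export
adaptTrajectory <- function(plan, correction, currentIndex) {
  stopifnot(is(plan, "ApproachPlan"), is(correction, "AdaptiveCorrection"))
  if (vnorm(correction@axis - plan@axis) > 1e-9)
    paStop("correction was computed for a different axis than the plan",
           "invalidParameter")
  if (currentIndex < 1L || currentIndex > nrow(plan@waypoints))
    paStop("currentIndex outside the plan", "invalidParameter")
  shift <- correction@targetDisplacement - correction@tipLateralOffset
  cur <- plan@waypoints[currentIndex, ]
  newStart <- cur + shift
  newTerm <- plan@termination + shift
  if (newTerm[3L] < plan@piaZ)
    paStop("corrected termination lies above the pia; refusing to adapt",
           "adaptRefused")
  if (vnorm(shift) < .Machine$double.eps) return(plan)
  steps <- discretizeAxial(newStart, newTerm, plan@params$stepSize)
  wp <- rbind(plan@waypoints[seq_len(currentIndex), , drop = FALSE],
              newStart, steps)
  dimnames(wp) <- NULL
  ph <- c(plan@phase[seq_len(currentIndex)], "correct",
          rep("approach", nrow(steps)))
  new("ApproachPlan", waypoints = wp, phase = ph,
      entryPoint = plan@entryPoint + shift, termination = newTerm,
      target = plan@target + correction@targetDisplacement,
      piaZ = plan@piaZ, axis = plan@axis, params = plan@params)
}
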