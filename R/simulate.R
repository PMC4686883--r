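# Closed-loop approach simulation: physics (deflection/drift) -> imaging
# (phantom rendering) -> analysis (localization) -> control (planning and
# adaptive correction), mirroring the acquisition loop of an image-guided
# approach to a target neuron.

#' Simulate one pipette approach
#'
#' Plans a trajectory from the nominal tip to the nominal target and
#' executes it against a simulated manipulator implementing the given
#' deflection model. With the adaptive strategy, execution pauses at an
#' intermediate point along the route (fraction \code{adaptiveFraction} of
#' the intracortical depth), renders fresh substacks around the expected
#' tip and target, re-localizes both, and adapts the remaining trajectory;
#' the naive strategy advances straight to the planned termination. A
#' localization failure mid-approach is surfaced as a failed approach
#' (success = FALSE), not hidden.
#'
#' @param spec a \linkS4class{PhantomSpec}; the first cell is the target.
#' @param deflection a \linkS4class{DeflectionModel}.
#' @param strategy \code{"adaptive"} or \code{"naive"}.
#' @param params an \code{\link{approachParams}} list.
#' @param piaZ depth of the pia plane, microns (default 30).
#' @param localization \code{"image"} (render + localize) or
#'   \code{"truth"} (feed ground truth to the correction, for isolating
#'   the control geometry from localization error).
#' @param tipRoiHalfExtent,targetRoiHalfExtent micron half-extents of the
#'   re-imaging regions of interest.
#' @param seed seed for the rendering noise at the adaptive step.
#' @return a list record: \code{strategy}, \code{success}, \code{failure}
#'   (message or NULL), \code{final} (\linkS4class{SeparationMetrics}),
#'   \code{finalTip}, \code{finalTarget}, \code{rLateralAtAdaptive},
#'   \code{snr}, \code{log} (command log), \code{plan}.
#' @export
simulateApproach <- function(spec, deflection = deflectionModel(),
                             strategy = c("adaptive", "naive"),
                             params = approachParams(), piaZ = 30,
                             localization = c("image", "truth"),
                             tipRoiHalfExtent = c(25, 25, 20),
                             targetRoiHalfExtent = c(25, 25, 20),
                             seed = spec@seed) {
  strategy <- match.arg(strategy)
  localization <- match.arg(localization)
  stopifnot(is(spec, "PhantomSpec"), is(deflection, "DeflectionModel"))
  geom <- spec@geometry
  axis <- approachAxis(geom)
  nominalTip <- tipPosition(geom)
  nominalTarget <- spec@cells[[1L]]$center
  plan <- planTrajectory(nominalTip, nominalTarget, piaZ, geom, params)
  sink <- simulatedManipulator(deflection, piaZ)
  physTip <- function(cmd) cmd + deflectionAt(deflection, cmd[3L] - piaZ)
  actualTarget <- function(depth)
    nominalTarget + targetDriftAt(deflection, depth)
  snr <- with(spec@noise, if (type == "none") Inf else
    spec@pipettePeak / sqrt(readSigma^2 +
      if (type == "poisson") spec@backgroundLevel else 0))

  finish <- function(plan, log, rAtAdaptive, success = TRUE, failure = NULL) {
    lastCmd <- as.numeric(tail2(log))
    tip <- physTip(lastCmd)
    tgt <- actualTarget(lastCmd[3L] - piaZ)
    list(strategy = strategy, success = success, failure = failure,
         final = decomposeSeparation(tip, tgt, axis), finalTip = tip,
         finalTarget = tgt, rLateralAtAdaptive = rAtAdaptive, snr = snr,
         log = log, plan = plan)
  }

  if (strategy == "naive") {
    log <- executePlan(plan, sink)
    return(finish(plan, log, NA_real_))
  }

  # adaptive: pause at the first approach waypoint at or below the
  # adaptive depth
  wp <- waypoints(plan)
  ph <- phases(plan)
  termDepth <- plan@termination[3L] - piaZ
  pauseDepth <- piaZ + params$adaptiveFraction * termDepth
  idx <- which(ph == "approach" & wp[, 3L] >= pauseDepth)
  pause <- if (length(idx)) idx[1L] else nrow(wp) - 1L
  pause <- min(pause, nrow(wp) - 1L)  # keep at least one step to go
  log1 <- executePlan(plan, sink, toIndex = pause)
  cmd <- wp[pause, ]
  tipNow <- physTip(cmd)
  tgtNow <- actualTarget(cmd[3L] - piaZ)
  rAtAdaptive <- rLateral(decomposeSeparation(tipNow, tgtNow, axis))

  if (localization == "image") {
    shot <- renderStack(spec, deflection = tipNow - nominalTip,
                        cellShift = tgtNow - nominalTarget,
                        region = list(center = cmd,
                                      halfExtent = tipRoiHalfExtent),
                        seed = seed)
    measuredTip <- tryCatch(locateTip(shot$pipette, geom),
                            pipetteAimError = function(e) e)
    shot2 <- renderStack(spec, deflection = tipNow - nominalTip,
                         cellShift = tgtNow - nominalTarget,
                         region = list(center = nominalTarget,
                                       halfExtent = targetRoiHalfExtent),
                         seed = seed + 1L)
    measuredTarget <- tryCatch(locateTarget(shot2$cells, nominalTarget),
                               pipetteAimError = function(e) e)
    if (inherits(measuredTip, "condition") ||
        inherits(measuredTarget, "condition")) {
      msg <- paste(vapply(Filter(function(x) inherits(x, "condition"),
                                 list(measuredTip, measuredTarget)),
                          conditionMessage, character(1L)), collapse = "; ")
      return(finish(plan, log1, rAtAdaptive, success = FALSE, failure = msg))
    }
  } else {
    measuredTip <- tipNow
    measuredTarget <- tgtNow
  }

  corr <- computeCorrection(expectedTip = cmd, measuredTip = measuredTip,
                            originalTarget = nominalTarget,
                            measuredTarget = measuredTarget, axis = axis)
  plan2 <- tryCatch(adaptTrajectory(plan, corr, pause),
                    pipetteAimError = function(e) e)
  if (inherits(plan2, "condition"))
    return(finish(plan, log1, rAtAdaptive, success = FALSE,
                  failure = conditionMessage(plan2)))
  log2 <- executePlan(plan2, sink, fromIndex = pause + 1L)
  finish(plan2, rbind(log1, log2), rAtAdaptive)
}

tail2 <- function(log) log[nrow(log), c("cx", "cy", "cz")]

#' Simulate a batch of seeded approaches
#'
#' Draws a per-approach lateral deflection and target displacement
#' (independent Gaussian components in the plane perpendicular to the
#' pipette axis), simulates each approach with \code{\link{simulateApproach}},
#' and tabulates final separation metrics per approach. Reported
#' \code{rAxial} is unsigned.
#'
#' @param n number of approaches.
#' @param strategy \code{"adaptive"} or \code{"naive"}.
#' @param deflectionSigma sd (microns) of each lateral deflection
#'   component; default 5.
#' @param driftSigma sd (microns) of each lateral target-displacement
#'   component; default 4.
#' @param spec scene description; default \code{\link{batchScene}()}.
#' @param params approach parameters.
#' @param piaZ pia depth, microns.
#' @param localization passed to \code{\link{simulateApproach}}.
#' @param seed master seed; per-approach seeds are derived from it.
#' @return a data.frame (one row per approach) with columns \code{id},
#'   \code{strategy}, \code{rLateral}, \code{rAxial}, \code{rTotal},
#'   \code{rLateralAtAdaptive}, \code{success}, \code{snr}, and the final
#'   tip-minus-target vector \code{dx, dy, dz}.
#' @export
simulateBatch <- function(n = 100, strategy = c("adaptive", "naive"),
                          deflectionSigma = 5, driftSigma = 4,
                          spec = batchScene(), params = approachParams(),
                          piaZ = 30,
                          localization = c("image", "truth"), seed = 1L) {
  strategy <- match.arg(strategy)
  localization <- match.arg(localization)
  axis <- approachAxis(spec@geometry)
  B <- lateralBasis(axis)
  draws <- withSeed(seed, list(
    defl = matrix(rnorm(2L * n, sd = deflectionSigma), n, 2L),
    drift = matrix(rnorm(2L * n, sd = driftSigma), n, 2L),
    seeds = sample.int(2^30, n)))
  rows <- lapply(seq_len(n), function(i) {
    model <- deflectionModel(
      lateral = draws$defl[i, 1L] * B[1L, ] + draws$defl[i, 2L] * B[2L, ],
      targetDrift = draws$drift[i, 1L] * B[1L, ] + draws$drift[i, 2L] * B[2L, ])
    rec <- simulateApproach(spec, model, strategy, params, piaZ,
                            localization, seed = draws$seeds[i])
    data.frame(id = i, strategy = strategy,
               rLateral = rLateral(rec$final),
               rAxial = abs(rAxial(rec$final)),
               rTotal = rTotal(rec$final),
               rLateralAtAdaptive = rec$rLateralAtAdaptive,
               success = rec$success, snr = rec$snr,
               dx = rec$finalTip[1L] - rec$finalTarget[1L],
               dy = rec$finalTip[2L] - rec$finalTarget[2L],
               dz = rec$finalTip[3L] - rec$finalTarget[3L])
  })
  do.call(rbind, rows)
}

#' Reference scene for batch simulations
#'
#' A 256 x 256 x 150 stack at (1.23, 1.23, 2) um voxels with the pia plane
#' at z = 30 um, one target soma (radius 5 um) 150 um below the pia, and
#' the pipette starting on the nominal approach line above the pia. The
#' pipette channel carries a faint detector noise floor so that the
#' percentile normalization of the tip pipeline is well defined even when
#' photon noise is disabled.
#'
#' @param target target soma center, microns.
#' @param piaZ pia depth, microns.
#' @param tipStartZ starting depth of the tip (above the pia), microns.
#' @param noise noise model list, see \linkS4class{PhantomSpec}.
#' @param ... further arguments to \code{\link{phantomSpec}}.
#' @return a \linkS4class{PhantomSpec}.
#' @export
batchScene <- function(target = c(250, 157.4, 180), piaZ = 30,
                       tipStartZ = 20,
                       noise = list(type = "gaussian", readSigma = 2), ...) {
  axis <- axisFromAngles(31, 0)
  tip <- target - (target[3L] - tipStartZ) / axis[3L] * axis
  phantomSpec(tip = tip,
              cells = list(list(center = target, radius = 5, peak = 150)),
              noise = noise, ...)
}
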