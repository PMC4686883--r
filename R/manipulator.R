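# Execution of approach plans against a manipulator command sink.
#
# A manipulator is any function taking an absolute micron-space position
# (length-3 numeric) and returning the acknowledged position, or NULL to
# signal rejection. This contract is all a hardware adapter would need to
# implement; only a simulated manipulator ships with the package.

#' Execute an approach plan
#'
#' Sends one absolute move command per waypoint, in order, and records
#' commanded vs acknowledged positions. A rejected command (manipulator
#' returns \code{NULL}) aborts execution; the partial log is returned with
#' attribute \code{aborted = TRUE}.
#'
#' @param plan an \linkS4class{ApproachPlan}.
#' @param manipulator a command sink function, e.g.
#'   \code{\link{simulatedManipulator}}.
#' @param fromIndex first waypoint to execute (default 1).
#' @param toIndex last waypoint to execute (default all).
#' @return a data.frame log with columns \code{index}, \code{phase},
#'   commanded \code{cx, cy, cz} and acknowledged \code{ax, ay, az}.
#' @export
executePlan <- function(plan, manipulator, fromIndex = 1L,
                        toIndex = nrow(waypoints(plan))) {
  stopifnot(is(plan, "ApproachPlan"), is.function(manipulator))
  wp <- waypoints(plan)
  ph <- phases(plan)
  rows <- vector("list", max(0L, toIndex - fromIndex + 1L))
  aborted <- FALSE
  n <- 0L
  for (i in seq_len(nrow(wp))) {
    if (i < fromIndex || i > toIndex) next
    ack <- manipulator(wp[i, ])
    if (is.null(ack)) { aborted <- TRUE; break }
    n <- n + 1L
    rows[[n]] <- data.frame(index = i, phase = ph[i],
                            cx = wp[i, 1L], cy = wp[i, 2L], cz = wp[i, 3L],
                            ax = ack[1L], ay = ack[2L], az = ack[3L])
  }
  log <- if (n) do.call(rbind, rows[seq_len(n)]) else
    data.frame(index = integer(0L), phase = character(0L),
               cx = numeric(0L), cy = numeric(0L), cz = numeric(0L),
               ax = numeric(0L), ay = numeric(0L), az = numeric(0L))
  if (aborted) {
    warning("manipulator rejected a command; execution aborted")
    attr(log, "aborted") <- TRUE
  }
  log
}

#' Simulated manipulator with a deflection model
#'
#' Returns a command sink whose acknowledged position is the commanded
#' position plus the lateral tip deflection predicted by \code{model} at
#' the commanded insertion depth below \code{piaZ} (zero above the pia).
#'
#' @param model a \linkS4class{DeflectionModel}.
#' @param piaZ depth of the pia plane, microns.
#' @return a function usable with \code{\link{executePlan}}.
#' @export
simulatedManipulator <- function(model = deflectionModel(), piaZ = 0) {
  force(model); force(piaZ)
  function(cmd) {
    cmd <- assertPoint3(cmd, "command")
    cmd + deflectionAt(model, cmd[3L] - piaZ)
  }
}
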