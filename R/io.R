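# TIFF stack I/O with voxel-size metadata, JSON plan serialization and
# JSON-lines localization reports.

#' Write image stacks to a multi-page TIFF with a JSON sidecar
#'
#' Channels are written sequentially, one 32-bit float page per z plane,
#' with intensities rescaled to [0, 1] by a common factor. A JSON sidecar
#' (\code{<path>.json}) records the shape, channel roles, voxel size,
#' origin and intensity scale so that \code{\link{readStackTIFF}} restores
#' the stacks exactly.
#'
#' @param stacks an \linkS4class{ImageStack} or a (possibly named) list of
#'   them sharing one grid.
#' @param path output TIFF path.
#' @return invisibly, the sidecar path.
#' @export
writeStackTIFF <- function(stacks, path) {
  if (is(stacks, "ImageStack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1L,
            all(vapply(stacks, is, logical(1L), "ImageStack")))
  ref <- stacks[[1L]]
  d <- dim(ref@intensities)
  scale <- max(1e-12, max(vapply(stacks, function(s) max(s@intensities),
                                 numeric(1L))))
  pages <- list()
  for (s in stacks) {
    if (!identical(dim(s@intensities), d))
      paStop("all channels must share one grid", "invalidParameter")
    for (k in seq_len(d[3L]))
      pages[[length(pages) + 1L]] <- s@intensities[, , k] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(shape = d, nChannels = length(stacks),
               channelRoles = vapply(stacks, channelRole, character(1L)),
               voxelSize = ref@voxelSize, origin = ref@origin,
               intensityScale = scale)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read image stacks written by \code{\link{writeStackTIFF}}
#'
#' Voxel size is taken from the JSON sidecar when present, else from the
#' TIFF resolution tags, else from \code{voxelSize}.
#'
#' @param path TIFF path.
#' @param voxelSize fallback voxel size (microns) when no metadata exists.
#' @param nChannels fallback channel count when no sidecar exists.
#' @return a list of \linkS4class{ImageStack}s, one per channel.
#' @export
readStackTIFF <- function(path, voxelSize = c(1.23, 1.23, 2),
                          nChannels = 1L) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  if (is.null(meta)) {
    info <- attributes(pages[[1L]])
    res <- c(info$x.resolution %||% NA_real_, info$y.resolution %||% NA_real_)
    vsxy <- if (all(is.finite(res)) && all(res > 0)) {
      # resolution tags are pixels per unit (cm by convention here)
      u <- info$resolution.unit %||% "cm"
      fac <- if (identical(u, "inch")) 25400 else 10000
      fac / res
    } else voxelSize[c(1L, 2L)]
    meta <- list(shape = c(dim(pages[[1L]])[1:2],
                           length(pages) %/% nChannels),
                 nChannels = nChannels,
                 channelRoles = rep("unknown", nChannels),
                 voxelSize = c(vsxy, voxelSize[3L]), origin = c(0, 0, 0),
                 intensityScale = 1)
  }
  d <- as.integer(meta$shape)
  lapply(seq_len(meta$nChannels), function(ch) {
    a <- array(0, d)
    for (k in seq_len(d[3L])) {
      pg <- pages[[(ch - 1L) * d[3L] + k]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # grayscale stored flat
      a[, , k] <- pg
    }
    imageStack(a * meta$intensityScale, meta$voxelSize, meta$origin,
               meta$channelRoles[ch])
  })
}

#' Serialize an approach plan to JSON (and back)
#'
#' Waypoints are stored in microns with their phase labels, together with
#' the entry point, termination, target, pia depth, axis and parameters.
#'
#' @param plan an \linkS4class{ApproachPlan}.
#' @param path JSON output path.
#' @return invisibly, \code{path}.
#' @export
writePlanJSON <- function(plan, path) {
  stopifnot(is(plan, "ApproachPlan"))
  obj <- list(waypoints = unname(apply(plan@waypoints, 1L, as.numeric,
                                       simplify = FALSE)),
              phase = plan@phase, entryPoint = plan@entryPoint,
              termination = plan@termination, target = plan@target,
              piaZ = plan@piaZ, axis = plan@axis, params = plan@params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePlanJSON
#' @export
readPlanJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  wp <- if (is.matrix(obj$waypoints)) obj$waypoints
  else if (is.list(obj$waypoints)) do.call(rbind, obj$waypoints)
  else matrix(obj$waypoints, ncol = 3L, byrow = TRUE)
  new("ApproachPlan", waypoints = wp, phase = obj$phase,
      entryPoint = obj$entryPoint, termination = obj$termination,
      target = obj$target, piaZ = obj$piaZ, axis = obj$axis,
      params = as.list(obj$params))
}

#' Append a localization report as a JSON line
#'
#' One JSON object per line: timestamp, kind, estimate, parameters and
#' quality metrics, suitable for post-hoc auditing of a session.
#'
#' @param path report file (created if missing).
#' @param kind "tip" or "target".
#' @param estimate micron estimate (the \code{"quality"} attribute, if
#'   present, is included).
#' @param params the parameter list used.
#' @return invisibly, \code{path}.
#' @export
writeLocalizationReport <- function(path, kind, estimate, params = list()) {
  entry <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                kind = kind, estimate = as.numeric(estimate),
                quality = attr(estimate, "quality"),
                params = unclass(params))
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA,
                           null = "null")
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
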