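# Summary statistics over approach records: mean +/- SD (not SEM) per
# metric, click-precision mean square deviation, outlier filtering and
# target-centered point-cloud export.

#' Summarize approach precision
#'
#' Per strategy and metric, reports mean, standard deviation (sample SD,
#' denominator n - 1, following the convention of reporting SD rather than
#' SEM to show the spread of pipette-target distances) and N. Rows flagged
#' \code{excluded} (see \code{\link{outlierFilter}}) are kept in the table
#' but left out of the statistics. Axial distances are reported unsigned;
#' the distance to the cell surface is the center distance minus the soma
#' radius (negative values mean the tip ended inside the soma).
#'
#' @param table data.frame with columns \code{strategy}, \code{rLateral},
#'   \code{rAxial}, \code{rTotal} (one row per approach), optionally
#'   \code{excluded}.
#' @param cellRadius soma radius used for the surface distance, microns
#'   (default 5, a typical mouse neuron cell body).
#' @return a data.frame with columns \code{strategy}, \code{metric},
#'   \code{mean}, \code{sd}, \code{n}; \code{sd} is NA for a single
#'   approach.
#' @examples
#' tb <- data.frame(strategy = "adaptive", rLateral = c(3, 4, 5),
#'                  rAxial = c(10, 11, 12), rTotal = c(10.4, 11.7, 13))
#' summarizeApproaches(tb)
#' @export
summarizeApproaches <- function(table, cellRadius = 5) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    paStop("table must contain at least one approach", "invalidParameter")
  excl <- if ("excluded" %in% names(table)) table$excluded else
    rep(FALSE, nrow(table))
  tb <- table[!excl, , drop = FALSE]
  if (nrow(tb) == 0L)
    paStop("all approaches are excluded", "invalidParameter")
  tb$rAxial <- abs(tb$rAxial)
  tb$surfaceDistance <- tb$rTotal - cellRadius
  metrics <- c("rLateral", "rAxial", "rTotal", "surfaceDistance")
  out <- do.call(rbind, lapply(split(tb, tb$strategy), function(g) {
    do.call(rbind, lapply(metrics, function(m) {
      x <- g[[m]]
      data.frame(strategy = g$strategy[1L], metric = m, mean = mean(x),
                 sd = if (length(x) > 1L) sd(x) else NA_real_,
                 n = length(x))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Format a precision result the conventional way
#'
#' @param metric metric name, e.g. "r_lateral".
#' @param mean,sd,n summary values.
#' @param unit unit string, default "um".
#' @return e.g. \code{"r_lateral = 5.04 +/- 2.93 um, N = 11"}.
#' @export
formatPrecision <- function(metric, mean, sd, n, unit = "um") {
  sprintf("%s = %.2f +/- %.2f %s, N = %d", metric, mean, sd, unit,
          as.integer(n))
}

#' Mean square deviation of repeated localizations
#'
#' Root-mean-square distance of repeated localizations of the same object
#' from their centroid: the click-precision metric.
#'
#' @param points n x 3 matrix of micron positions.
#' @return MSD in microns.
#' @export
meanSquareDeviation <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    paStop("need at least two localizations", "invalidParameter")
  ctr <- colMeans(points)
  sqrt(mean(rowSums(sweep(points, 2L, ctr)^2)))
}

#' Flag outlier approaches by final distance
#'
#' Approaches whose final center distance exceeds \code{threshold} are
#' flagged \code{excluded = TRUE} but kept in the table; downstream
#' statistics skip them. The default threshold of 40 um is distance-based;
#' the recorded SNR column allows auditing whether flagged rows coincide
#' with low imaging quality.
#'
#' @param table approach table with an \code{rTotal} column.
#' @param threshold microns, must be > 0.
#' @return the table with an \code{excluded} column; attribute
#'   \code{nExcluded}.
#' @export
outlierFilter <- function(table, threshold = 40) {
  if (!(threshold > 0)) paStop("threshold must be > 0", "invalidParameter")
  table$excluded <- table$rTotal > threshold
  n <- sum(table$excluded)
  if (n > 0L)
    message(n, " approach(es) beyond ", threshold,
            " um flagged as excluded")
  attr(table, "nExcluded") <- n
  table
}

#' Export final pipette positions as a target-centered point cloud
#'
#' Rotates the final tip-minus-target vectors so the pipette axis maps to
#' the +x reference direction; the target sits at the origin and a sphere
#' of \code{somaRadius} microns approximates the soma. The rotation is
#' rigid, so the lateral/axial decomposition of every point is preserved.
#'
#' @param table approach table with columns \code{dx, dy, dz} (final tip
#'   minus final target, microns).
#' @param axis unit pipette axis the approaches were flown along.
#' @param somaRadius reference soma radius, microns (default 5).
#' @return data.frame with rotated coordinates \code{u} (along the axis),
#'   \code{v}, \code{w} (lateral plane) plus \code{strategy} if present;
#'   attribute \code{somaRadius}.
#' @export
pointCloudExport <- function(table, axis, somaRadius = 5) {
  axis <- assertUnitAxis(axis)
  R <- rotationAlign(axis, c(1, 0, 0))
  d <- as.matrix(table[, c("dx", "dy", "dz")])
  u <- d %*% t(R)
  out <- data.frame(u = u[, 1L], v = u[, 2L], w = u[, 3L])
  if ("strategy" %in% names(table)) out$strategy <- table$strategy
  attr(out, "somaRadius") <- somaRadius
  out
}

#' Plot a target-centered point cloud
#'
#' Simple base-graphics rendering of \code{\link{pointCloudExport}}
#' output: axial position along the pipette axis vs lateral offset, with
#' the reference soma circle at the origin.
#'
#' @param cloud output of \code{\link{pointCloudExport}}.
#' @param ... further arguments passed to \code{plot}.
#' @return invisibly, the plotted data.frame.
#' @export
plotPointCloud <- function(cloud, ...) {
  lat <- sqrt(cloud$v^2 + cloud$w^2)
  r <- attr(cloud, "somaRadius") %||% 5
  plot(cloud$u, lat, xlab = "axial position along pipette axis (um)",
       ylab = "lateral distance from axis (um)",
       xlim = range(c(cloud$u, -r, r)), ylim = c(0, max(lat, r) * 1.05),
       pch = 17, ...)
  th <- seq(0, pi, length.out = 100L)
  graphics::lines(r * cos(th), r * sin(th), col = "grey50")
  abline(h = 0, col = "grey80")
  invisible(cloud)
}
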