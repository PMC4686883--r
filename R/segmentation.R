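# Threshold segmentation and connected components.

#' Connected-component labelling
#'
#' 8-connected for 2D images (matrices), 26-connected for 3D arrays.
#' Labels are assigned in raster-scan discovery order starting at 1, so
#' label order is deterministic and usable for tie-breaking.
#'
#' @param mask logical matrix or 3D array.
#' @return integer matrix/array of component labels (0 = background).
#' @export
labelComponents <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || !length(d) %in% c(2L, 3L))
    paStop("mask must be a logical matrix or 3D array", "invalidParameter")
  d3 <- if (length(d) == 2L) c(d, 1L) else d
  lab <- label_components(as.logical(mask), as.integer(d3))
  array(lab, dim = d)
}

#' Segment the largest suprathreshold object in a 2D image
#'
#' Thresholds the image at \code{thresholdFraction} of its maximum and
#' returns the largest 8-connected component with strictly more than
#' \code{minPixels} pixels. If no component qualifies (or the image is all
#' zero) an empty mask is returned with attribute \code{found = FALSE}.
#'
#' @param image numeric matrix (typically a maximum intensity projection).
#' @param thresholdFraction fraction of the image maximum, default 0.90.
#' @param minPixels minimum object size (exclusive), default 10.
#' @return logical matrix selecting one object; attributes \code{found}
#'   and \code{size}.
#' @export
segmentLargest <- function(image, thresholdFraction = 0.90, minPixels = 10) {
  if (!is.matrix(image) || !length(image))
    paStop("image must be a non-empty matrix", "invalidParameter")
  if (!(thresholdFraction > 0 && thresholdFraction <= 1))
    paStop("thresholdFraction must lie in (0, 1]", "invalidParameter")
  empty <- function() {
    m <- matrix(FALSE, nrow(image), ncol(image))
    attr(m, "found") <- FALSE
    attr(m, "size") <- 0L
    m
  }
  mx <- max(image)
  if (mx <= 0) return(empty())
  bw <- image >= thresholdFraction * mx
  lab <- labelComponents(bw)
  if (!any(bw)) return(empty())
  sizes <- tabulate(lab[lab > 0L])
  ok <- which(sizes > minPixels)
  if (!length(ok)) return(empty())
  pick <- ok[which.max(sizes[ok])]
  m <- lab == pick
  attr(m, "found") <- TRUE
  attr(m, "size") <- sizes[pick]
  m
}
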