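#' @name pipetteAim-generics
#' @title Accessor generics
#' @description Accessors for the core S4 classes. All distances are in
#'   microns in the common stack frame.
#' @param x an object.
#' @keywords internal
NULL

#' @rdname pipetteAim-generics
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname pipetteAim-generics
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname pipetteAim-generics
#' @export
setGeneric("stackOrigin", function(x) standardGeneric("stackOrigin"))

#' @rdname pipetteAim-generics
#' @export
setGeneric("channelRole", function(x) standardGeneric("channelRole"))

#' @rdname pipetteAim-generics
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname pipetteAim-generics
#' @export
setGeneric("tipPosition", function(x) standardGeneric("tipPosition"))

#' @rdname pipetteAim-generics
#' @export
setGeneric("approachAxis", function(x) standardGeneric("approachAxis"))

#' @rdname pipetteAim-generics
#' @export
setGeneric("waypoints", function(x) standardGeneric("waypoints"))

#' @rdname pipetteAim-generics
#' @export
setGeneric("phases", function(x) standardGeneric("phases"))

#' @rdname pipetteAim-generics
#' @export
setGeneric("rLateral", function(x) standardGeneric("rLateral"))

#' @rdname pipetteAim-generics
#' @export
setGeneric("rAxial", function(x) standardGeneric("rAxial"))

#' @rdname pipetteAim-generics
#' @export
setGeneric("rTotal", function(x) standardGeneric("rTotal"))
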