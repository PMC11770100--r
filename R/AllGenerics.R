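#' @rdname VideoStack-class
#' @param object,x a package object.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname VideoStack-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname VideoStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname VideoStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trace-class
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname Trace-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname MModeMatrix-class
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname MModeMatrix-class
#' @export
setGeneric("lineEndpoints", function(x) standardGeneric("lineEndpoints"))

#' @rdname EllipseFit-class
#' @export
setGeneric("longAxis", function(x) standardGeneric("longAxis"))

#' @rdname EllipseFit-class
#' @export
setGeneric("shortAxis", function(x) standardGeneric("shortAxis"))

#' @rdname EllipseFit-class
#' @export
setGeneric("ellipseCenter", function(x) standardGeneric("ellipseCenter"))

#' @rdname EllipseFit-class
#' @export
setGeneric("ellipseAngle", function(x) standardGeneric("ellipseAngle"))

#' @rdname Calibration-class
#' @export
setGeneric("slope", function(x) standardGeneric("slope"))

#' @rdname Calibration-class
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' @rdname Calibration-class
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname CardiacReport-class
#' @export
setGeneric("hr", function(x) standardGeneric("hr"))

#' @rdname CardiacReport-class
#' @export
setGeneric("fac", function(x) standardGeneric("fac"))

#' @rdname CardiacReport-class
#' @export
setGeneric("sv", function(x) standardGeneric("sv"))

#' @rdname CardiacReport-class
#' @export
setGeneric("co", function(x) standardGeneric("co"))

#' @rdname CardiacReport-class
#' @export
setGeneric("cycles", function(x) standardGeneric("cycles"))

#' @rdname CardiacReport-class
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))
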