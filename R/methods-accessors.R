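# Constructors, accessors and show() methods for the S4 containers.

#' @rdname VideoStack-class
#' @param frames numeric 3-D array `[y, x, t]` or a list of equally sized
#'   matrices; values on the 0--255 scale.
#' @param frameRate frames per second.
#' @param pixelSize microns per pixel.
#' @return `VideoStack()` returns a [VideoStack-class] object.
#' @examples
#' v <- VideoStack(array(128, dim = c(8, 8, 4)), frameRate = 35, pixelSize = 1)
#' nFrames(v)
#' @export
VideoStack <- function(frames, frameRate, pixelSize = 1) {
    if (is.list(frames))
        frames <- simplify2array(frames)
    if (is.matrix(frames))
        frames <- array(frames, dim = c(dim(frames), 1L))
    new("VideoStack", frames = frames, frameRate = as.numeric(frameRate),
        pixelSize = as.numeric(pixelSize))
}

#' @rdname VideoStack-class
#' @export
setMethod("frames", "VideoStack", function(x) x@frames)

#' @rdname VideoStack-class
#' @export
setMethod("frameRate", "VideoStack", function(x) x@frameRate)

#' @rdname VideoStack-class
#' @export
setMethod("pixelSize", "VideoStack", function(x) x@pixelSize)

#' @rdname VideoStack-class
#' @export
setMethod("nFrames", "VideoStack", function(x) dim(x@frames)[3L])

#' @rdname VideoStack-class
#' @param i frame index.
#' @export
getFrame <- function(x, i) {
    stopifnot(is(x, "VideoStack"), i >= 1L, i <= nFrames(x))
    x@frames[, , i]
}

setMethod("show", "VideoStack", function(object) {
    d <- dim(object@frames)
    cat(sprintf(
        "VideoStack: %d frame(s) of %d x %d px, %.3g fps, %.3g um/px\n",
        d[3L], d[1L], d[2L], object@frameRate, object@pixelSize))
    cat(sprintf("  duration %.3g s, intensity range [%.1f, %.1f]\n",
        d[3L] / object@frameRate, min(object@frames), max(object@frames)))
})

#' @rdname Trace-class
#' @param values numeric sample vector.
#' @param samplingRate sampling rate in Hz.
#' @return `Trace()` returns a [Trace-class] object.
#' @examples
#' tr <- Trace(sin(2 * pi * 2 * seq(0, 5, by = 1 / 35)), samplingRate = 35)
#' samplingRate(tr)
#' @export
Trace <- function(values, samplingRate) {
    new("Trace", values = as.numeric(values),
        samplingRate = as.numeric(samplingRate))
}

#' @rdname Trace-class
#' @export
setMethod("traceValues", "Trace", function(x) x@values)

#' @rdname Trace-class
#' @export
setMethod("samplingRate", "Trace", function(x) x@samplingRate)

#' @rdname Trace-class
#' @export
setMethod("length", "Trace", function(x) length(x@values))

setMethod("show", "Trace", function(object) {
    cat(sprintf("Trace: %d samples at %.3g Hz (%.3g s), range [%.4g, %.4g]\n",
        length(object@values), object@samplingRate,
        (length(object@values) - 1L) / object@samplingRate,
        min(object@values), max(object@values)))
})

#' @rdname MModeMatrix-class
#' @param intensity numeric matrix `[t, x]`.
#' @param endpoints 2x2 matrix of line endpoints, rows = points, cols = (x, y).
#' @param frameRate source frame rate in frames/s.
#' @return `MModeMatrix()` returns an [MModeMatrix-class] object.
#' @export
MModeMatrix <- function(intensity, endpoints, frameRate) {
    new("MModeMatrix", intensity = intensity,
        endpoints = matrix(as.numeric(endpoints), 2L, 2L),
        frameRate = as.numeric(frameRate))
}

#' @rdname MModeMatrix-class
#' @export
setMethod("intensityMatrix", "MModeMatrix", function(x) x@intensity)

#' @rdname MModeMatrix-class
#' @export
setMethod("lineEndpoints", "MModeMatrix", function(x) x@endpoints)

#' @rdname MModeMatrix-class
#' @export
setMethod("frameRate", "MModeMatrix", function(x) x@frameRate)

setMethod("show", "MModeMatrix", function(object) {
    cat(sprintf(
        "MModeMatrix: %d frames x %d positions along (%.1f,%.1f)-(%.1f,%.1f)\n",
        nrow(object@intensity), ncol(object@intensity),
        object@endpoints[1L, 1L], object@endpoints[1L, 2L],
        object@endpoints[2L, 1L], object@endpoints[2L, 2L]))
})

#' @rdname EllipseFit-class
#' @param center numeric (x, y) in pixels.
#' @param dLong,dShort axis diameters in microns.
#' @param angle long-axis orientation in degrees.
#' @param residual RMS point-to-ellipse distance in pixels.
#' @return `EllipseFit()` returns an [EllipseFit-class] object.
#' @export
EllipseFit <- function(center, dLong, dShort, angle, residual = NA_real_) {
    new("EllipseFit", center = as.numeric(center), dLong = as.numeric(dLong),
        dShort = as.numeric(dShort), angle = as.numeric(angle),
        residual = as.numeric(residual))
}

#' @rdname EllipseFit-class
#' @export
setMethod("longAxis", "EllipseFit", function(x) x@dLong)

#' @rdname EllipseFit-class
#' @export
setMethod("shortAxis", "EllipseFit", function(x) x@dShort)

#' @rdname EllipseFit-class
#' @export
setMethod("ellipseCenter", "EllipseFit", function(x) x@center)

#' @rdname EllipseFit-class
#' @export
setMethod("ellipseAngle", "EllipseFit", function(x) x@angle)

setMethod("show", "EllipseFit", function(object) {
    cat(sprintf(
        "EllipseFit: D_L = %.2f um, D_S = %.2f um, angle %.1f deg,\n",
        object@dLong, object@dShort, object@angle))
    cat(sprintf("  center (%.2f, %.2f) px, RMS residual %.3g px\n",
        object@center[1L], object@center[2L], object@residual))
})

#' @rdname Calibration-class
#' @param slope absorbance per uM.
#' @param intercept absorbance offset.
#' @param rSquared coefficient of determination.
#' @param concRange calibrated concentration range (min, max) in uM.
#' @return `Calibration()` returns a [Calibration-class] object.
#' @export
Calibration <- function(slope, intercept, rSquared, concRange) {
    new("Calibration", slope = as.numeric(slope),
        intercept = as.numeric(intercept), rSquared = as.numeric(rSquared),
        concRange = as.numeric(concRange))
}

#' @rdname Calibration-class
#' @export
setMethod("slope", "Calibration", function(x) x@slope)

#' @rdname Calibration-class
#' @export
setMethod("intercept", "Calibration", function(x) x@intercept)

#' @rdname Calibration-class
#' @export
setMethod("rSquared", "Calibration", function(x) x@rSquared)

setMethod("show", "Calibration", function(object) {
    cat(sprintf(
        "Calibration: A = %.6g * C + %.6g (R^2 = %.4f), range %g-%g uM\n",
        object@slope, object@intercept, object@rSquared,
        object@concRange[1L], object@concRange[2L]))
})

#' @rdname CardiacReport-class
#' @param hr heart rate, beats/min.
#' @param fac fractional area change, percent.
#' @param sv stroke volume, nL/beat.
#' @param cycles per-cycle measurement data.frame.
#' @param qc character vector of quality-control flags.
#' @return `CardiacReport()` returns a [CardiacReport-class] object with
#'   `co` set to `sv * hr`.
#' @export
CardiacReport <- function(hr, fac, sv, cycles = data.frame(),
                          qc = character()) {
    new("CardiacReport", hr = as.numeric(hr), fac = as.numeric(fac),
        sv = as.numeric(sv), co = as.numeric(sv) * as.numeric(hr),
        cycles = cycles, qc = qc)
}

#' @rdname CardiacReport-class
#' @export
setMethod("hr", "CardiacReport", function(x) x@hr)

#' @rdname CardiacReport-class
#' @export
setMethod("fac", "CardiacReport", function(x) x@fac)

#' @rdname CardiacReport-class
#' @export
setMethod("sv", "CardiacReport", function(x) x@sv)

#' @rdname CardiacReport-class
#' @export
setMethod("co", "CardiacReport", function(x) x@co)

#' @rdname CardiacReport-class
#' @export
setMethod("cycles", "CardiacReport", function(x) x@cycles)

#' @rdname CardiacReport-class
#' @export
setMethod("qcFlags", "CardiacReport", function(x) x@qc)

setMethod("show", "CardiacReport", function(object) {
    cat("CardiacReport\n")
    cat(sprintf("  HR : %.1f beats/min\n", object@hr))
    cat(sprintf("  FAC: %.2f %%\n", object@fac))
    cat(sprintf("  SV : %.4f nL/beat\n", object@sv))
    cat(sprintf("  CO : %.2f nL/min\n", object@co))
    cat(sprintf("  %d complete cycle(s)", nrow(object@cycles)))
    if (length(object@qc))
        cat("; qc: ", paste(object@qc, collapse = ", "), sep = "")
    cat("\n")
})
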