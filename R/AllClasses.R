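#' @import methods
NULL

#' VideoStack: an ordered grayscale frame stack
#'
#' Container for time-lapse grayscale video as used throughout the cardiac
#' pipeline: a 3-D numeric array of frames (rows = y, columns = x, third
#' dimension = time), the acquisition frame rate and the pixel size.
#' Pixel values are on the 8-bit scale (0--255) but stored as numeric so
#' that filtered/derived stacks need no re-quantisation.
#'
#' @slot frames numeric 3-D array `[y, x, t]`, values in `[0, 255]`.
#' @slot frameRate frames per second (> 0).
#' @slot pixelSize microns per pixel (> 0).
#'
#' @seealso [VideoStack()] for the constructor, [generateHeartVideo()] for a
#'   synthetic source, [readVideoTIFF()] to load a multi-page TIFF.
#' @name VideoStack-class
#' @aliases VideoStack-class
#' @exportClass VideoStack
setClass("VideoStack",
    representation(
        frames = "array",
        frameRate = "numeric",
        pixelSize = "numeric"
    )
)

setValidity("VideoStack", function(object) {
    msg <- NULL
    d <- dim(object@frames)
    if (length(d) != 3L)
        msg <- c(msg, "'frames' must be a 3-D array [y, x, t]")
    else if (d[1L] < 1L || d[2L] < 1L)
        msg <- c(msg, "frames must be non-empty images")
    if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
        object@frameRate <= 0)
        msg <- c(msg, "'frameRate' must be a single positive number")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        msg <- c(msg, "'pixelSize' must be a single positive number")
    if (length(object@frames) && (min(object@frames) < 0 ||
        max(object@frames) > 255))
        msg <- c(msg, "pixel values must lie in [0, 255]")
    if (is.null(msg)) TRUE else msg
})

#' Trace: a 1-D intensity time series
#'
#' A sampled intensity trace (raw grayscale or a filtered/normalised
#' derivative) together with its sampling rate. Produced by
#' [extractRoiTrace()] and transformed by [bandpass()] and
#' [normalizeTrace()].
#'
#' @slot values numeric vector of finite samples (length >= 2).
#' @slot samplingRate sampling frequency in Hz (> 0).
#'
#' @name Trace-class
#' @aliases Trace-class
#' @exportClass Trace
setClass("Trace",
    representation(
        values = "numeric",
        samplingRate = "numeric"
    )
)

setValidity("Trace", function(object) {
    msg <- NULL
    if (length(object@values) < 2L)
        msg <- c(msg, "a trace needs at least 2 samples")
    if (any(!is.finite(object@values)))
        msg <- c(msg, "trace values must be finite")
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0)
        msg <- c(msg, "'samplingRate' must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' MModeMatrix: intensity along a scan line over time
#'
#' Motion-mode (M-mode) representation of wall motion: grayscale intensity
#' sampled along a fixed line, one row per frame, one column per position
#' along the line. Mirrors echocardiographic M-mode display.
#'
#' @slot intensity numeric matrix `[t, x]`, values in `[0, 255]`.
#' @slot endpoints numeric 2x2 matrix; rows are the two line endpoints,
#'   columns are (x, y) pixel coordinates.
#' @slot frameRate frames per second of the source video.
#'
#' @name MModeMatrix-class
#' @aliases MModeMatrix-class
#' @exportClass MModeMatrix
setClass("MModeMatrix",
    representation(
        intensity = "matrix",
        endpoints = "matrix",
        frameRate = "numeric"
    )
)

setValidity("MModeMatrix", function(object) {
    msg <- NULL
    if (!is.numeric(object@intensity))
        msg <- c(msg, "'intensity' must be numeric")
    if (length(object@intensity) &&
        (min(object@intensity) < 0 || max(object@intensity) > 255))
        msg <- c(msg, "intensity values must lie in [0, 255]")
    if (!identical(dim(object@endpoints), c(2L, 2L)))
        msg <- c(msg, "'endpoints' must be a 2x2 matrix of (x, y) coordinates")
    if (is.null(msg)) TRUE else msg
})

#' EllipseFit: an ellipse fitted to the ventricular edge
#'
#' Result of the direct least-squares conic fit to edge points of the
#' segmented ventricle. Axis lengths are full diameters in microns
#' (converted via the pixel size); the centre stays in pixel coordinates.
#'
#' @slot center numeric (x, y) centre in pixels.
#' @slot dLong long-axis diameter in microns.
#' @slot dShort short-axis diameter in microns (`dLong >= dShort > 0`).
#' @slot angle orientation of the long axis in degrees, measured from the
#'   +x axis toward +y (y points down image rows), in `[0, 180)`.
#' @slot residual root-mean-square point-to-ellipse (Sampson) distance, px.
#'
#' @name EllipseFit-class
#' @aliases EllipseFit-class
#' @exportClass EllipseFit
setClass("EllipseFit",
    representation(
        center = "numeric",
        dLong = "numeric",
        dShort = "numeric",
        angle = "numeric",
        residual = "numeric"
    )
)

setValidity("EllipseFit", function(object) {
    msg <- NULL
    if (length(object@center) != 2L || any(!is.finite(object@center)))
        msg <- c(msg, "'center' must be finite (x, y)")
    if (!isTRUE(object@dShort > 0))
        msg <- c(msg, "axis lengths must be positive")
    if (!isTRUE(object@dLong >= object@dShort))
        msg <- c(msg, "'dLong' must be >= 'dShort'")
    if (is.null(msg)) TRUE else msg
})

#' Calibration: a Beer--Lambert concentration--absorbance line
#'
#' Ordinary least-squares fit of absorbance against concentration used to
#' verify in-droplet drug concentrations from spectrophotometric readings.
#'
#' @slot slope absorbance per micromolar (> 0 for a usable calibration).
#' @slot intercept absorbance at zero concentration.
#' @slot rSquared coefficient of determination in `[0, 1]`.
#' @slot concRange range (min, max) of calibrated concentrations, uM.
#'
#' @name Calibration-class
#' @aliases Calibration-class
#' @exportClass Calibration
setClass("Calibration",
    representation(
        slope = "numeric",
        intercept = "numeric",
        rSquared = "numeric",
        concRange = "numeric"
    )
)

setValidity("Calibration", function(object) {
    msg <- NULL
    if (!isTRUE(object@slope > 0))
        msg <- c(msg, "'slope' must be positive")
    if (!isTRUE(object@rSquared >= 0 && object@rSquared <= 1 + 1e-12))
        msg <- c(msg, "'rSquared' must lie in [0, 1]")
    if (length(object@concRange) != 2L ||
        object@concRange[1L] > object@concRange[2L])
        msg <- c(msg, "'concRange' must be (min, max)")
    if (is.null(msg)) TRUE else msg
})

#' CardiacReport: per-recording cardiac function summary
#'
#' The end product of [analyzeCardiac()]: heart rate from the filtered
#' region-of-interest trace, plus fractional area change, stroke volume and
#' cardiac output averaged over complete cardiac cycles, the per-cycle
#' measurements themselves, and quality-control flags.
#'
#' @slot hr heart rate, beats/min.
#' @slot fac fractional area change, percent (0--100).
#' @slot sv stroke volume, nL/beat.
#' @slot co cardiac output, nL/min; always `sv * hr` exactly.
#' @slot cycles data.frame of per-cycle end-diastolic/end-systolic axis
#'   lengths (`ldD`, `ldS`, `sdD`, `sdS`, microns), areas (`eda`, `esa`,
#'   square microns), volumes (`edv`, `esv`, nL), `fac` (%), `sv` (nL) and
#'   the delimiting frame indices (`edFrame`, `esFrame`, `endFrame`).
#' @slot qc character vector of quality-control flags.
#'
#' @name CardiacReport-class
#' @aliases CardiacReport-class
#' @exportClass CardiacReport
setClass("CardiacReport",
    representation(
        hr = "numeric",
        fac = "numeric",
        sv = "numeric",
        co = "numeric",
        cycles = "data.frame",
        qc = "character"
    )
)

setValidity("CardiacReport", function(object) {
    msg <- NULL
    if (!isTRUE(object@fac >= 0 && object@fac <= 100))
        msg <- c(msg, "'fac' must lie in [0, 100] percent")
    if (!isTRUE(all.equal(object@co, object@sv * object@hr,
            tolerance = 1e-12)))
        msg <- c(msg, "'co' must equal sv * hr")
    if (is.null(msg)) TRUE else msg
})
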