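#' Synthetic beating-heart video with full ground truth
#'
#' Renders a filled elliptical ventricle on a lighter background whose long
#' and short axes oscillate between end-systolic and end-diastolic extremes
#' with a raised-cosine waveform at the requested heart rate, then adds
#' clipped Gaussian pixel noise. The returned ground truth records the exact
#' per-frame axis lengths and every derived cardiac indicator, so the whole
#' quantification pipeline can be validated against known values.
#'
#' The waveform for each axis is
#' `D(t) = D_s + (D_d - D_s) * (1 + cos(2 * pi * f * t)) / 2` with
#' `f = heartRate / 60` Hz, giving a smooth cycle with a single diastolic
#' maximum (at phase 0) and a single systolic minimum per period. Frame `k`
#' is rendered at `t = (k - 1) / frameRate`, so the first frame is at
#' end-diastole.
#'
#' @param frameRate acquisition rate, frames/s; must exceed the Nyquist
#'   limit `2 * heartRate / 60`.
#' @param duration recording length, s; must cover at least one cardiac
#'   period.
#' @param imageSize frame size `c(height, width)` in pixels.
#' @param pixelSize microns per pixel.
#' @param ldD,ldS long-axis diameter at end-diastole / end-systole, microns.
#' @param sdD,sdS short-axis diameter at end-diastole / end-systole, microns.
#' @param heartRate true heart rate, beats/min.
#' @param angle ellipse orientation, degrees from +x toward +y.
#' @param intensityInside,intensityOutside grayscale of ventricle lumen and
#'   background (0--255). Defaults render a dark ventricle on a light field,
#'   the bright-field appearance; swap them to invert polarity.
#' @param noiseSd standard deviation of additive Gaussian pixel noise in
#'   grayscale units (clipped to `[0, 255]`).
#' @param seed integer RNG seed; identical seed and parameters reproduce the
#'   stack bit for bit. `NULL` leaves the RNG stream untouched.
#' @return A list with components:
#' \describe{
#'   \item{video}{a [VideoStack-class] of `round(duration * frameRate)`
#'     frames.}
#'   \item{truth}{a list with `heartRate` (beats/min), per-frame `time`,
#'     `dLong`, `dShort` (um), the ellipse `center` (px) and `angle`, and
#'     the derived `eda`, `esa` (um^2), `edv`, `esv` (nL), `fac` (%),
#'     `sv` (nL/beat) and `co` (nL/min), all computed with the package's
#'     own formula layer from the extreme axis values.}
#' }
#' @examples
#' ph <- generateHeartVideo(duration = 3, noiseSd = 0, seed = 1)
#' ph$truth$fac
#' nFrames(ph$video)
#' @seealso [analyzeCardiac()] to recover the indicators from the video.
#' @export
generateHeartVideo <- function(frameRate = 35, duration = 10,
                               imageSize = c(192, 192), pixelSize = 1,
                               ldD = 150, ldS = 100, sdD = 100, sdS = 70,
                               heartRate = 150, angle = 0,
                               intensityInside = 60, intensityOutside = 180,
                               noiseSd = 0, seed = 1L) {
    stopifnot(length(imageSize) == 2L, all(imageSize >= 4))
    if (!(ldD > ldS && ldS > 0) || !(sdD > sdS && sdS > 0))
        stop("axis extremes must satisfy ldD > ldS > 0 and sdD > sdS > 0")
    if (ldD < sdD)
        stop("the long axis must be at least as long as the short axis")
    if (heartRate <= 0)
        stop("'heartRate' must be positive")
    ints <- c(intensityInside, intensityOutside)
    if (any(ints < 0 | ints > 255))
        stop("intensities must lie in [0, 255]")
    fNyq <- 2 * heartRate / 60
    if (frameRate <= fNyq)
        stop(sprintf(
            "frame rate %.4g fps cannot sample %.4g beats/min: need > %.4g fps",
            frameRate, heartRate, fNyq))
    if (duration < 60 / heartRate)
        stop(sprintf(
            "duration %.4g s is shorter than one cardiac period (%.4g s)",
            duration, 60 / heartRate))
    h <- as.integer(imageSize[1L]); w <- as.integer(imageSize[2L])
    n <- round(duration * frameRate)
    tt <- (seq_len(n) - 1L) / frameRate
    f <- heartRate / 60
    osc <- (1 + cos(2 * pi * f * tt)) / 2
    dLong <- ldS + (ldD - ldS) * osc
    dShort <- sdS + (sdD - sdS) * osc
    cx <- (w + 1) / 2
    cy <- (h + 1) / 2
    stack <- array(intensityOutside, dim = c(h, w, n))
    for (k in seq_len(n)) {
        mask <- .ellipseMask(h, w, cx, cy,
            dLong[k] / 2 / pixelSize, dShort[k] / 2 / pixelSize, angle)
        fr <- stack[, , k]
        fr[mask] <- intensityInside
        stack[, , k] <- fr
    }
    if (noiseSd > 0)
        stack <- .withSeed(seed, .clip255(
            stack + stats::rnorm(length(stack), sd = noiseSd)))
    eda <- ventricleArea(ldD, sdD)
    esa <- ventricleArea(ldS, sdS)
    edv <- ventricleVolume(ldD, sdD)
    esv <- ventricleVolume(ldS, sdS)
    svTrue <- strokeVolume(edv, esv)
    list(
        video = VideoStack(stack, frameRate = frameRate,
            pixelSize = pixelSize),
        truth = list(
            heartRate = heartRate, time = tt,
            dLong = dLong, dShort = dShort,
            center = c(cx, cy), angle = angle,
            eda = eda, esa = esa, edv = edv, esv = esv,
            fac = fractionalAreaChange(eda, esa),
            sv = svTrue, co = cardiacOutput(svTrue, heartRate)))
}

#' Synthetic larva frame with eye features and ground truth
#'
#' Renders an elongated larva body along a channel axis with two dark
#' circular eye blobs offset toward the head, emulating the scene an
#' overhead camera sees in an observation channel. The sign of `eyeOffset`
#' encodes the travel orientation: positive offsets place the eyes ahead of
#' the body centroid along the +axis direction (head-forward), negative
#' offsets behind it (tail-forward). This sign convention is defined here
#' and reused unchanged by [determineOrientation()].
#'
#' @param imageSize frame size `c(height, width)` in pixels.
#' @param bodyCenter body centroid `c(x, y)` in pixels; default image centre.
#' @param bodyAxisAngle channel axis direction, degrees from +x toward +y.
#' @param bodyLength body blob length along the axis, px.
#' @param eyeOffset signed distance of the eye pair from the body centre
#'   along the axis, px; `|eyeOffset| < bodyLength / 2`.
#' @param eyeRadius eye blob radius, px.
#' @param eyeIntensity,bodyIntensity,backgroundIntensity grayscale levels;
#'   eyes must be the darkest feature (`eyeIntensity < bodyIntensity`).
#' @param noiseSd additive Gaussian noise sd, grayscale units.
#' @param present if `FALSE`, render background only (empty channel).
#' @param seed integer RNG seed (see [generateHeartVideo()]).
#' @return A list with `image` (numeric matrix, 0--255) and `truth`: a list
#'   with `present`, `orientation` (`"head_forward"`, `"tail_forward"` or
#'   `"undetermined"` when `eyeOffset == 0`), `eyeCentroids` (2 x 2 matrix,
#'   columns x, y), `bodyCentroid` and `axisAngle`.
#' @examples
#' lv <- generateLarvaFrame(eyeOffset = 30, seed = 7)
#' lv$truth$orientation
#' @export
generateLarvaFrame <- function(imageSize = c(120, 200), bodyCenter = NULL,
                               bodyAxisAngle = 0, bodyLength = 120,
                               eyeOffset = 30, eyeRadius = 6,
                               eyeIntensity = 40, bodyIntensity = 120,
                               backgroundIntensity = 200,
                               noiseSd = 0, present = TRUE, seed = 1L) {
    stopifnot(length(imageSize) == 2L, all(imageSize >= 4))
    h <- as.integer(imageSize[1L]); w <- as.integer(imageSize[2L])
    if (eyeRadius <= 0)
        stop("'eyeRadius' must be positive")
    if (abs(eyeOffset) >= bodyLength / 2)
        stop("|eyeOffset| must be smaller than half the body length")
    if (eyeIntensity >= bodyIntensity)
        stop("eyes must be darker than the body (eyeIntensity < bodyIntensity)")
    img <- matrix(backgroundIntensity, h, w)
    truth <- list(present = FALSE, orientation = "undetermined",
        eyeCentroids = NULL, bodyCentroid = NULL, axisAngle = bodyAxisAngle)
    if (present) {
        if (is.null(bodyCenter))
            bodyCenter <- c((w + 1) / 2, (h + 1) / 2)
        th <- bodyAxisAngle * pi / 180
        u <- c(cos(th), sin(th))          # along-axis unit vector (x, y)
        vperp <- c(-sin(th), cos(th))
        eyeSep <- 1.25 * eyeRadius        # half inter-eye spacing
        eyeMid <- bodyCenter + eyeOffset * u
        eye1 <- eyeMid + eyeSep * vperp
        eye2 <- eyeMid - eyeSep * vperp
        for (e in list(eye1, eye2)) {
            if (e[1L] - eyeRadius < 1 || e[1L] + eyeRadius > w ||
                e[2L] - eyeRadius < 1 || e[2L] + eyeRadius > h)
                stop("eye blob falls outside the image bounds")
        }
        body <- .ellipseMask(h, w, bodyCenter[1L], bodyCenter[2L],
            bodyLength / 2, bodyLength / 6, bodyAxisAngle)
        img[body] <- bodyIntensity
        for (e in list(eye1, eye2)) {
            m <- .ellipseMask(h, w, e[1L], e[2L], eyeRadius, eyeRadius)
            img[m] <- eyeIntensity
        }
        truth <- list(
            present = TRUE,
            orientation = if (eyeOffset > 0) "head_forward"
                else if (eyeOffset < 0) "tail_forward" else "undetermined",
            eyeCentroids = rbind(eye1, eye2, deparse.level = 0),
            bodyCentroid = bodyCenter,
            axisAngle = bodyAxisAngle)
        colnames(truth$eyeCentroids) <- c("x", "y")
    }
    if (noiseSd > 0)
        img <- .withSeed(seed,
            .clip255(img + stats::rnorm(length(img), sd = noiseSd)))
    list(image = img, truth = truth)
}

#' Synthetic Beer--Lambert calibration table
#'
#' Generates `(concentration, absorbance)` pairs on a straight line with
#' optional Gaussian noise, emulating a spectrophotometric standard series.
#' The default concentrations are the five-standard series used for
#' methylene blue calibration (5, 20, 50, 80 and 110 uM).
#'
#' @param slope molar absorptivity line slope, absorbance per uM.
#' @param intercept absorbance at zero concentration.
#' @param concentrations standard concentrations, uM (non-empty).
#' @param noiseSd Gaussian noise sd on absorbance.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `concentration_uM` and `absorbance`.
#' @examples
#' generateCalibrationTable(slope = 0.01, noiseSd = 0)
#' @seealso [fitCalibration()]
#' @export
generateCalibrationTable <- function(slope = 0.01, intercept = 0,
                                     concentrations = c(5, 20, 50, 80, 110),
                                     noiseSd = 0, seed = 1L) {
    if (!length(concentrations))
        stop("'concentrations' must not be empty")
    if (any(concentrations < 0))
        stop("concentrations must be non-negative")
    a <- slope * concentrations + intercept
    if (noiseSd > 0)
        a <- .withSeed(seed,
            a + stats::rnorm(length(a), sd = noiseSd))
    data.frame(concentration_uM = concentrations, absorbance = a)
}
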