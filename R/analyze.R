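#' Full cardiac analysis of one recording
#'
#' End-to-end quantification of a ventricular recording, combining the two
#' measurement chains:
#'
#' 1. *Rate chain*: [extractRoiTrace()] over the ventricle ROI, zero-phase
#'    Butterworth [bandpass()], min-max [normalizeTrace()], peak-counted
#'    [heartRate()].
#' 2. *Geometry chain*: per-frame [segmentVentricle()] + [fitEllipse()]
#'    via [axisTimeseries()], cycle delimitation and end-diastolic /
#'    end-systolic measurement via [detectEdEs()], and the formula layer
#'    ([ventricleArea()], [fractionalAreaChange()], [ventricleVolume()],
#'    [strokeVolume()], [cardiacOutput()]).
#'
#' Per-cycle FAC and SV are averaged (arithmetic mean over complete
#' cycles; the incomplete terminal cycle is discarded by construction) and
#' CO is the mean SV times HR, so `co == sv * hr` holds exactly in every
#' report.
#'
#' When no `roi` is given, one is derived from the data: the ventricle is
#' segmented in the first usable frame and its bounding box, padded by 30%,
#' becomes both the trace ROI and the segmentation search window. The
#' padding matters for the rate chain — the ROI must include ground the
#' wall sweeps across, otherwise the mean grayscale would not oscillate.
#'
#' @param video a [VideoStack-class].
#' @param roi trace region `c(x, y, w, h)`; `NULL` for the auto ROI.
#' @param roiHint segmentation search window; defaults to `roi`.
#' @param band Butterworth band edges in Hz. The 0.2--2 Hz default suits
#'   resting larval rates up to ~120 beats/min; a QC flag
#'   (`hr_near_band_edge`) and a warning are raised when the estimated rate
#'   approaches the high edge, since faster hearts are attenuated there.
#' @param filterOrder Butterworth design order.
#' @param minProminence,minSeparation peak gates for [heartRate()].
#' @param ... passed to [segmentVentricle()] via [axisTimeseries()].
#' @return A [CardiacReport-class].
#' @examples
#' ph <- generateHeartVideo(duration = 4, heartRate = 120,
#'     imageSize = c(96, 96), ldD = 70, ldS = 48, sdD = 48, sdS = 34,
#'     seed = 1)
#' rep <- analyzeCardiac(ph$video)
#' rep
#' @export
analyzeCardiac <- function(video, roi = NULL, roiHint = NULL,
                           band = c(0.2, 2), filterOrder = 4,
                           minProminence = 0.2, minSeparation = 0.2, ...) {
    stopifnot(is(video, "VideoStack"))
    d <- dim(frames(video))
    qc <- character()
    if (is.null(roi)) {
        roi <- NULL
        for (k in unique(pmin(c(1L, d[3L] %/% 2L + 1L), d[3L]))) {
            edge <- tryCatch(segmentVentricle(frames(video)[, , k], ...),
                error = function(e) NULL)
            if (!is.null(edge)) {
                bx <- range(edge[, 1L]); by <- range(edge[, 2L])
                mw <- 0.3 * diff(bx); mh <- 0.3 * diff(by)
                x1 <- max(1, floor(bx[1L] - mw))
                y1 <- max(1, floor(by[1L] - mh))
                x2 <- min(d[2L], ceiling(bx[2L] + mw))
                y2 <- min(d[1L], ceiling(by[2L] + mh))
                roi <- c(x1, y1, x2 - x1 + 1, y2 - y1 + 1)
                break
            }
        }
        if (is.null(roi))
            stop("could not derive a ventricle ROI: segmentation failed")
    }
    if (is.null(roiHint))
        roiHint <- roi
    tr <- extractRoiTrace(video, roi)
    bpm <- estimateHeartRate(tr, band = band, order = filterOrder,
        minProminence = minProminence, minSeparation = minSeparation)
    qc <- c(qc, attr(bpm, "flags"))
    if (bpm / 60 >= 0.9 * band[2L]) {
        qc <- c(qc, "hr_near_band_edge")
        warning(sprintf(
            "estimated heart rate %.1f beats/min (%.2f Hz) is at or above the %g Hz band edge; the rate chain widened its filter band accordingly",
            bpm, bpm / 60, band[2L]))
    }
    ax <- axisTimeseries(video, roiHint, ...)
    nbad <- sum(!ax$ok)
    if (nbad > 0L)
        qc <- c(qc, sprintf("%d frame(s) dropped by segmentation", nbad))
    cyc <- detectEdEs(ax$dLong, ax$dShort, attr(ax, "samplingRate"))
    CardiacReport(hr = as.numeric(bpm), fac = mean(cyc$fac),
        sv = mean(cyc$sv), cycles = cyc, qc = qc)
}
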