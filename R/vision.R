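# Computer-vision chain for the screening control loop: presence detection
# in the loading channel, eye segmentation, orientation calls and per-frame
# coordinate tracking. All coordinates are 1-based (x = column, y = row,
# y increasing down the rows); angles are degrees from +x toward +y.
#
# Images are plain numeric matrices on the 0-255 scale; internally they are
# transposed and rescaled to EBImage's (x, y) / [0, 1] conventions.

.asEB <- function(image) {
    if (!is.matrix(image) || !length(image))
        stop("'image' must be a non-empty numeric matrix")
    t(image) / 255
}

#' Detect a larva in a single frame
#'
#' Presence detection as used on the loading-channel camera: blur lightly,
#' binarise with a dark-object convention, label connected components and
#' call the larva present when the largest component is big enough.
#'
#' @param image numeric matrix, grayscale 0--255.
#' @param threshold grayscale binarisation threshold (0--255); pixels darker
#'   than it are foreground. `NULL` (default) picks it by Otsu's method.
#'   With `darkObject = FALSE` the polarity is inverted.
#' @param minArea minimum component area in px^2 for a positive call.
#' @param blurSigma Gaussian pre-smoothing sigma in px.
#' @param darkObject logical; `TRUE` (default) treats dark pixels as object.
#' @param minContrast minimum grayscale separation between the candidate
#'   object and the background class; frames with less dynamic range than
#'   this are called empty, which keeps pure-noise frames from producing
#'   spurious detections.
#' @return A list with `present` (logical), `bbox` (`c(x, y, w, h)` or
#'   `NULL`), `area` (px^2) and `centroid` (`c(x, y)` or `NULL`).
#' @examples
#' lv <- generateLarvaFrame(seed = 3)
#' detectLarva(lv$image)$present
#' @export
detectLarva <- function(image, threshold = NULL, minArea = 50,
                        blurSigma = 1, darkObject = TRUE, minContrast = 20) {
    x <- .asEB(image)
    empty <- list(present = FALSE, bbox = NULL, area = 0, centroid = NULL)
    if (diff(range(x)) * 255 < minContrast)
        return(empty)
    if (blurSigma > 0)
        x <- EBImage::gblur(x, sigma = blurSigma)
    thr <- if (is.null(threshold)) EBImage::otsu(x) else threshold / 255
    mask <- if (darkObject) x < thr else x > thr
    if (abs(mean(x[mask]) - mean(x[!mask])) * 255 < minContrast)
        return(empty)
    lab <- EBImage::bwlabel(mask)
    nobj <- max(lab)
    if (nobj < 1L)
        return(empty)
    areas <- tabulate(lab[lab > 0], nbins = nobj)
    k <- which.max(areas)
    if (areas[k] < minArea)
        return(empty)
    idx <- which(lab == k, arr.ind = TRUE)   # col 1 = x, col 2 = y
    list(
        present = TRUE,
        bbox = c(x = min(idx[, 1L]), y = min(idx[, 2L]),
            w = diff(range(idx[, 1L])) + 1L,
            h = diff(range(idx[, 2L])) + 1L),
        area = areas[k],
        centroid = c(x = mean(idx[, 1L]), y = mean(idx[, 2L])))
}

#' Segment the eye features of a larva
#'
#' Morphological chain used to enhance and extract the darkest compact
#' features (the eyes): median filter, binarisation, erosion, dilation, in
#' that order, followed by size and circularity gates. At most the two
#' largest surviving components are returned.
#'
#' The default binarisation is a two-stage Otsu: a first threshold separates
#' the animal from the background, a second, computed on the animal pixels
#' only, isolates the darkest class (the eyes). A manual `threshold`
#' overrides both stages.
#'
#' @inheritParams detectLarva
#' @param medianRadius median filter radius in px (kernel `2r + 1` square).
#' @param threshold manual grayscale threshold (0--255) below which pixels
#'   count as eye candidates; `NULL` for the two-stage Otsu default.
#' @param brushSize diameter of the disc structuring element, px.
#' @param iterations erosion/dilation passes.
#' @param minArea,maxArea component area gates, px^2.
#' @param minCircularity minimum `4 * pi * area / perimeter^2`.
#' @return A numeric matrix with one row per detected eye (0, 1 or 2 rows)
#'   and columns `x`, `y`; component areas are attached as attribute
#'   `"areas"`.
#' @examples
#' lv <- generateLarvaFrame(seed = 3)
#' segmentEyes(lv$image)
#' @export
segmentEyes <- function(image, medianRadius = 1, threshold = NULL,
                        brushSize = 3, iterations = 1,
                        minArea = 5, maxArea = Inf, minCircularity = 0.4) {
    x <- .asEB(image)
    none <- matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("x", "y")))
    if (diff(range(x)) < 1e-8)
        return(none)
    if (medianRadius > 0)
        x <- EBImage::medianFilter(x, medianRadius)
    if (is.null(threshold)) {
        t1 <- EBImage::otsu(x)
        inside <- x < t1
        if (!any(inside) || diff(range(x[inside])) < 1e-8)
            return(none)
        t2 <- .otsuVec(x[inside])
        mask <- x < min(t1, t2)
    } else {
        mask <- x < threshold / 255
    }
    brush <- EBImage::makeBrush(brushSize, shape = "disc")
    for (i in seq_len(iterations)) mask <- EBImage::erode(mask, brush)
    for (i in seq_len(iterations)) mask <- EBImage::dilate(mask, brush)
    lab <- EBImage::bwlabel(mask)
    if (max(lab) < 1L)
        return(none)
    shp <- EBImage::computeFeatures.shape(lab)
    mom <- EBImage::computeFeatures.moment(lab)
    area <- shp[, "s.area"]
    perim <- pmax(shp[, "s.perimeter"], 1)
    circ <- 4 * pi * area / perim^2
    ok <- which(area >= minArea & area <= maxArea & circ >= minCircularity)
    if (!length(ok))
        return(none)
    ok <- ok[order(area[ok], decreasing = TRUE)]
    ok <- ok[seq_len(min(2L, length(ok)))]
    out <- cbind(x = mom[ok, "m.cx"], y = mom[ok, "m.cy"])
    attr(out, "areas") <- unname(area[ok])
    out
}

#' Decide head-forward vs tail-forward from eye position
#'
#' Projects the mean eye position and the body centroid onto the channel
#' axis direction. The call is `head_forward` when the eyes lead the body
#' centroid along the +axis by more than a dead-band `epsilon`,
#' `tail_forward` when they trail by more than `epsilon`, and
#' `undetermined` inside the dead-band or when no eyes were found.
#'
#' @param eyes matrix of eye centroids (rows, columns x/y) as returned by
#'   [segmentEyes()]; may have zero rows.
#' @param body body centroid `c(x, y)`.
#' @param axisAngle channel axis direction, degrees from +x toward +y.
#' @param epsilon dead-band half-width in px.
#' @return A list with `orientation` (one of `"head_forward"`,
#'   `"tail_forward"`, `"undetermined"`), `eyeCentroids`, `bodyCentroid`,
#'   `axisAngle` and the signed projected `lead` in px (NA with no eyes).
#' @examples
#' determineOrientation(rbind(c(130, 60), c(130, 70)), c(100, 65), 0)
#' @export
determineOrientation <- function(eyes, body, axisAngle = 0, epsilon = 2) {
    if (length(body) != 2L || any(!is.finite(body)))
        stop("'body' centroid must be finite (x, y)")
    call <- list(orientation = "undetermined", eyeCentroids = eyes,
        bodyCentroid = body, axisAngle = axisAngle, lead = NA_real_)
    if (is.null(eyes) || nrow(eyes) == 0L)
        return(call)
    th <- axisAngle * pi / 180
    u <- c(cos(th), sin(th))
    call$lead <- mean(eyes[, 1L] * u[1L] + eyes[, 2L] * u[2L]) -
        sum(body * u)
    if (call$lead > epsilon)
        call$orientation <- "head_forward"
    else if (call$lead < -epsilon)
        call$orientation <- "tail_forward"
    call
}

#' Full orientation call on a single frame
#'
#' Convenience composition of [detectLarva()], [segmentEyes()] and
#' [determineOrientation()]: detect the animal, locate its eyes and decide
#' the travel direction. When two eyes are found but lie further apart than
#' `maxEyeDistance`, the pair is treated as a mis-segmentation and the call
#' is `undetermined`.
#'
#' @inheritParams detectLarva
#' @inheritParams determineOrientation
#' @param maxEyeDistance maximum plausible inter-eye centroid distance, px
#'   (`Inf` disables the gate).
#' @param ... further arguments passed to [segmentEyes()].
#' @return As [determineOrientation()], plus `present`.
#' @examples
#' lv <- generateLarvaFrame(eyeOffset = -30, seed = 11)
#' orientLarva(lv$image)$orientation
#' @export
orientLarva <- function(image, axisAngle = 0, epsilon = 2,
                        maxEyeDistance = Inf, minArea = 50, ...) {
    det <- detectLarva(image, minArea = minArea)
    if (!det$present)
        return(list(present = FALSE, orientation = "undetermined",
            eyeCentroids = NULL, bodyCentroid = NULL,
            axisAngle = axisAngle, lead = NA_real_))
    eyes <- segmentEyes(image, ...)
    if (nrow(eyes) == 2L &&
        sqrt(sum((eyes[1L, ] - eyes[2L, ])^2)) > maxEyeDistance)
        return(list(present = TRUE, orientation = "undetermined",
            eyeCentroids = eyes, bodyCentroid = det$centroid,
            axisAngle = axisAngle, lead = NA_real_))
    c(present = TRUE,
      determineOrientation(eyes, det$centroid, axisAngle, epsilon))
}

#' Track larva coordinates across frames
#'
#' Pure per-frame measurement: runs [detectLarva()] on every frame and
#' records the centroid of the detected component; no motion model is
#' applied. Frames without a detection are marked absent.
#'
#' @param video a [VideoStack-class] or 3-D array `[y, x, t]`.
#' @param ... arguments passed to [detectLarva()].
#' @return A data.frame with one row per frame: `frame`, `x`, `y` (NA when
#'   absent) and `present`.
#' @examples
#' lv <- generateLarvaFrame(seed = 3)
#' v <- VideoStack(array(rep(lv$image, 3), c(dim(lv$image), 3)), 30)
#' trackLarva(v)
#' @export
trackLarva <- function(video, ...) {
    arr <- if (is(video, "VideoStack")) frames(video) else video
    n <- if (length(dim(arr)) == 3L) dim(arr)[3L] else 0L
    out <- data.frame(frame = seq_len(n), x = rep(NA_real_, n),
        y = rep(NA_real_, n), present = logical(n))
    for (k in seq_len(n)) {
        det <- detectLarva(arr[, , k], ...)
        if (det$present) {
            out$x[k] <- det$centroid[1L]
            out$y[k] <- det$centroid[2L]
            out$present[k] <- TRUE
        }
    }
    out
}
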