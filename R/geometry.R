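#' Segment the ventricle in one frame
#'
#' Dark-object segmentation of the ventricular lumen: light Gaussian
#' smoothing, Otsu binarisation (within the ROI hint when given), largest
#' connected component, hole filling, and extraction of the boundary pixel
#' chain.
#'
#' @param frame numeric matrix, grayscale 0--255.
#' @param roiHint optional `c(x, y, w, h)` rectangle restricting the search.
#' @param blurSigma Gaussian smoothing sigma, px.
#' @param threshold manual grayscale threshold (0--255); `NULL` for Otsu.
#' @param darkObject logical; `TRUE` segments dark-on-light (bright-field).
#' @return A numeric matrix of boundary coordinates (columns `x`, `y`,
#'   1-based, in full-frame coordinates) with attributes `centroid`
#'   (component centroid) and `area` (px^2).
#' @examples
#' ph <- generateHeartVideo(duration = 1, heartRate = 120, seed = 1)
#' b <- segmentVentricle(getFrame(ph$video, 1))
#' attr(b, "centroid")
#' @export
segmentVentricle <- function(frame, roiHint = NULL, blurSigma = 1,
                             threshold = NULL, darkObject = TRUE) {
    if (!is.matrix(frame) || !length(frame))
        stop("'frame' must be a non-empty numeric matrix")
    off <- c(0L, 0L)
    if (!is.null(roiHint)) {
        roiHint <- .checkRect(roiHint, nrow(frame), ncol(frame), "roiHint")
        frame <- frame[roiHint[2L]:(roiHint[2L] + roiHint[4L] - 1L),
                       roiHint[1L]:(roiHint[1L] + roiHint[3L] - 1L),
                       drop = FALSE]
        off <- c(roiHint[1L] - 1L, roiHint[2L] - 1L)
    }
    x <- .asEB(frame)
    if (diff(range(x)) < 1e-8)
        stop("no ventricle component found: frame has no contrast")
    if (blurSigma > 0)
        x <- EBImage::gblur(x, sigma = blurSigma)
    thr <- if (is.null(threshold)) EBImage::otsu(x) else threshold / 255
    mask <- if (darkObject) x < thr else x > thr
    lab <- EBImage::bwlabel(mask)
    if (max(lab) < 1L)
        stop("no ventricle component found")
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    k <- which.max(areas)
    obj <- EBImage::fillHull(lab == k)
    oc <- EBImage::ocontour(EBImage::bwlabel(obj))[[1L]]
    idx <- which(obj, arr.ind = TRUE)
    out <- cbind(x = oc[, 1L] + 1L + off[1L], y = oc[, 2L] + 1L + off[2L])
    attr(out, "centroid") <- c(x = mean(idx[, 1L]) + off[1L],
                               y = mean(idx[, 2L]) + off[2L])
    attr(out, "area") <- sum(obj)
    out
}

#' Direct least-squares ellipse fit to edge points
#'
#' Fits a conic constrained to be an ellipse to the boundary points of the
#' segmented ventricle, using the numerically stable partitioned form of
#' the direct algebraic least-squares fit (Halir & Flusser's formulation of
#' the Fitzgibbon constraint `4AC - B^2 = 1`). The fit is exact to machine
#' precision on noise-free conic points. Axis lengths are returned as full
#' diameters in microns.
#'
#' @param points numeric matrix of edge points, columns x and y, in pixels;
#'   at least 5 non-collinear points.
#' @param pixelSize microns per pixel.
#' @return An [EllipseFit-class]; `dLong >= dShort` is enforced by swapping
#'   axes, and the angle refers to the long axis, normalised to
#'   `[0, 180)` degrees.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 100)
#' pts <- cbind(60 + 75 * cos(th), 60 + 50 * sin(th))
#' fitEllipse(pts)
#' @export
fitEllipse <- function(points, pixelSize = 1) {
    points <- as.matrix(points)
    if (nrow(points) < 5L)
        stop("need at least 5 points to fit an ellipse")
    if (any(!is.finite(points)))
        stop("edge points must be finite")
    mx <- mean(points[, 1L]); my <- mean(points[, 2L])
    x <- points[, 1L] - mx
    y <- points[, 2L] - my
    sv <- svd(cbind(x, y))$d
    if (sv[2L] < 1e-10 * max(sv[1L], 1))
        stop("edge points are collinear: no ellipse is defined")
    d1 <- cbind(x^2, x * y, y^2)
    d2 <- cbind(x, y, 1)
    s1 <- crossprod(d1)
    s2 <- crossprod(d1, d2)
    s3 <- crossprod(d2)
    tmat <- -solve(s3, t(s2))
    m <- s1 + s2 %*% tmat
    m <- rbind(m[3L, ] / 2, -m[2L, ], m[1L, ] / 2)
    ev <- eigen(m)
    vec <- Re(ev$vectors)
    cond <- 4 * vec[1L, ] * vec[3L, ] - vec[2L, ]^2
    j <- which(cond > 0)
    if (!length(j))
        stop("points do not determine an ellipse")
    a1 <- vec[, j[1L]]
    conic <- c(a1, as.vector(tmat %*% a1))   # A B C D E F, centred coords
    A <- conic[1L]; B <- conic[2L]; C <- conic[3L]
    D <- conic[4L]; E <- conic[5L]; F <- conic[6L]
    den <- B^2 - 4 * A * C                   # < 0 for an ellipse
    cx <- (2 * C * D - B * E) / den
    cy <- (2 * A * E - B * D) / den
    num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
    rt <- sqrt((A - C)^2 + B^2)
    semi1 <- -sqrt(num * (A + C + rt)) / den
    semi2 <- -sqrt(num * (A + C - rt)) / den
    theta <- atan2(C - A - rt, B)            # major-axis direction
    semiMaj <- max(semi1, semi2)
    semiMin <- min(semi1, semi2)
    angle <- theta * 180 / pi
    angle <- angle %% 180
    # RMS Sampson distance as a geometric residual proxy
    q <- A * x^2 + B * x * y + C * y^2 + D * x + E * y + F
    g <- sqrt((2 * A * x + B * y + D)^2 + (B * x + 2 * C * y + E)^2)
    res <- sqrt(mean((q / pmax(g, .Machine$double.eps))^2))
    EllipseFit(center = c(cx + mx, cy + my),
        dLong = 2 * semiMaj * pixelSize,
        dShort = 2 * semiMin * pixelSize,
        angle = angle, residual = res)
}

#' Build an M-mode matrix along a scan line
#'
#' Motion-mode representation: samples the grayscale intensity along a
#' fixed line (bilinear interpolation, one sample per pixel of line length)
#' in every frame and stacks the profiles as rows, so wall motion appears
#' as bright/dark bands drifting through time — the light-microscopy
#' analogue of M-mode echocardiography.
#'
#' @param video a [VideoStack-class].
#' @param line line endpoints, either `c(x1, y1, x2, y2)` or a 2x2 matrix
#'   with rows `(x, y)`; must have positive length and lie inside the
#'   frame.
#' @return An [MModeMatrix-class] of dimension frames x samples.
#' @examples
#' ph <- generateHeartVideo(duration = 2, heartRate = 120, seed = 1)
#' mm <- buildMMode(ph$video, c(17, 96, 176, 96))
#' dim(intensityMatrix(mm))
#' @export
buildMMode <- function(video, line) {
    stopifnot(is(video, "VideoStack"))
    if (is.matrix(line)) line <- c(t(line))
    if (length(line) != 4L || any(!is.finite(line)))
        stop("'line' must be (x1, y1, x2, y2)")
    p1 <- line[1:2]; p2 <- line[3:4]
    len <- sqrt(sum((p2 - p1)^2))
    if (len <= 0)
        stop("scan line has zero length")
    d <- dim(frames(video))
    if (any(c(p1, p2) < 1) || p1[1L] > d[2L] || p2[1L] > d[2L] ||
        p1[2L] > d[1L] || p2[2L] > d[1L])
        stop("scan line endpoints lie outside the frame")
    ns <- ceiling(len) + 1L
    s <- seq(0, 1, length.out = ns)
    xs <- p1[1L] + s * (p2[1L] - p1[1L])
    ys <- p1[2L] + s * (p2[2L] - p1[2L])
    x0 <- pmin(pmax(floor(xs), 1L), d[2L] - 1L)
    y0 <- pmin(pmax(floor(ys), 1L), d[1L] - 1L)
    fx <- xs - x0
    fy <- ys - y0
    arr <- frames(video)
    n <- d[3L]
    out <- matrix(0, n, ns)
    i00 <- cbind(y0, x0)
    i01 <- cbind(y0, x0 + 1L)
    i10 <- cbind(y0 + 1L, x0)
    i11 <- cbind(y0 + 1L, x0 + 1L)
    for (k in seq_len(n)) {
        fr <- arr[, , k]
        out[k, ] <- fr[i00] * (1 - fx) * (1 - fy) +
            fr[i01] * fx * (1 - fy) +
            fr[i10] * (1 - fx) * fy +
            fr[i11] * fx * fy
    }
    MModeMatrix(out, rbind(p1, p2), frameRate(video))
}

#' Per-frame ventricular axis time series
#'
#' Runs [segmentVentricle()] and [fitEllipse()] on every frame, giving the
#' long- and short-axis diameter series in microns at the video frame
#' rate. Frames where segmentation or fitting fails are flagged and carry
#' `NA` axes (a gap), not an error; only an entirely unusable video stops.
#'
#' @param video a [VideoStack-class].
#' @param roiHint optional `c(x, y, w, h)` search rectangle.
#' @param ... passed to [segmentVentricle()].
#' @return A data.frame with columns `frame`, `time` (s), `dLong`, `dShort`
#'   (um), `ok` (logical); the sampling rate and pixel size are attached as
#'   attributes.
#' @examples
#' ph <- generateHeartVideo(duration = 1, heartRate = 120, seed = 1)
#' ax <- axisTimeseries(ph$video)
#' range(ax$dLong)
#' @export
axisTimeseries <- function(video, roiHint = NULL, ...) {
    stopifnot(is(video, "VideoStack"))
    n <- nFrames(video)
    if (n < 2L)
        stop("need at least 2 frames")
    out <- data.frame(frame = seq_len(n),
        time = (seq_len(n) - 1L) / frameRate(video),
        dLong = NA_real_, dShort = NA_real_, ok = FALSE)
    for (k in seq_len(n)) {
        fit <- tryCatch({
            edge <- segmentVentricle(frames(video)[, , k], roiHint, ...)
            fitEllipse(edge, pixelSize = pixelSize(video))
        }, error = function(e) NULL)
        if (!is.null(fit)) {
            out$dLong[k] <- longAxis(fit)
            out$dShort[k] <- shortAxis(fit)
            out$ok[k] <- TRUE
        }
    }
    if (!any(out$ok))
        stop("no usable frames: ventricle segmentation failed everywhere")
    attr(out, "samplingRate") <- frameRate(video)
    attr(out, "pixelSize") <- pixelSize(video)
    out
}

#' Detect end-diastole / end-systole and measure each cycle
#'
#' Delimits cardiac cycles by successive diastolic maxima of the
#' (lightly smoothed) ellipse-area series `pi/4 * dLong * dShort`, then
#' reads the long and short axes at the area maximum (end-diastole) and
#' minimum (end-systole) of each cycle — both axes are read at a common
#' frame, as a sonographer would on an M-mode trace. Areas and volumes
#' follow from the axis pairs via [ventricleArea()] and
#' [ventricleVolume()].
#'
#' @param dLong,dShort axis diameter series in microns (`NA` gaps are
#'   linearly interpolated).
#' @param samplingRate series sampling rate, Hz.
#' @param minProminence peak prominence gate on the `[0, 1]`-rescaled area
#'   series.
#' @param minSeparation minimum spacing of diastolic maxima, s.
#' @param smoothWindow moving-average window (odd, samples); default
#'   `max(3, round(samplingRate / 10))` rounded up to odd.
#' @return A data.frame with one row per complete cycle: `edFrame`,
#'   `esFrame`, `endFrame`, `ldD`, `ldS`, `sdD`, `sdS` (um), `eda`, `esa`
#'   (um^2), `edv`, `esv` (nL), `fac` (%), `sv` (nL).
#' @examples
#' ph <- generateHeartVideo(duration = 3, heartRate = 120, seed = 1)
#' cyc <- detectEdEs(ph$truth$dLong, ph$truth$dShort, 35)
#' colMeans(cyc[, c("ldD", "sdS")])
#' @export
detectEdEs <- function(dLong, dShort, samplingRate,
                       minProminence = 0.2, minSeparation = 0.25,
                       smoothWindow = NULL) {
    stopifnot(length(dLong) == length(dShort), samplingRate > 0)
    n <- length(dLong)
    idx <- seq_len(n)
    fill <- function(v) {
        if (anyNA(v)) {
            ok <- !is.na(v)
            if (sum(ok) < 2L)
                stop("too few usable samples in the axis series")
            v <- stats::approx(idx[ok], v[ok], idx, rule = 2)$y
        }
        v
    }
    dLong <- fill(dLong)
    dShort <- fill(dShort)
    area <- ventricleArea(dLong, dShort)
    if (diff(range(area)) == 0)
        stop("constant area series: no cardiac cycles present")
    if (is.null(smoothWindow)) {
        smoothWindow <- max(3L, round(samplingRate / 10))
        if (smoothWindow %% 2L == 0L) smoothWindow <- smoothWindow + 1L
    }
    hw <- smoothWindow %/% 2L
    padded <- c(rep(area[1L], hw), area, rep(area[n], hw))
    sm <- as.numeric(stats::filter(padded, rep(1 / smoothWindow,
        smoothWindow), sides = 2L))[hw + idx]
    smn <- (sm - min(sm)) / diff(range(sm))
    pk <- .findPeaks(smn, minProminence, round(minSeparation * samplingRate))
    if (length(pk) < 2L)
        stop("fewer than one complete cardiac cycle detected")
    cyc <- lapply(seq_len(length(pk) - 1L), function(i) {
        a <- pk[i]; b <- pk[i + 1L]
        edWin <- max(1L, a - hw):min(n, a + hw)   # refine on the raw series
        ed <- edWin[which.max(area[edWin])]
        esWin <- a:b
        es <- esWin[which.min(area[esWin])]
        data.frame(edFrame = ed, esFrame = es, endFrame = b,
            ldD = dLong[ed], ldS = dLong[es],
            sdD = dShort[ed], sdS = dShort[es])
    })
    cyc <- do.call(rbind, cyc)
    cyc$eda <- ventricleArea(cyc$ldD, cyc$sdD)
    cyc$esa <- ventricleArea(cyc$ldS, cyc$sdS)
    cyc$edv <- ventricleVolume(cyc$ldD, cyc$sdD)
    cyc$esv <- ventricleVolume(cyc$ldS, cyc$sdS)
    cyc$fac <- fractionalAreaChange(cyc$eda, pmin(cyc$esa, cyc$eda))
    cyc$sv <- strokeVolume(cyc$edv, pmin(cyc$esv, cyc$edv))
    cyc
}
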