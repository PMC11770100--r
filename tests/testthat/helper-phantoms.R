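# Shared fixtures and independent oracles, built in code at test time.

# A small, fast beating-heart phantom (96 x 96 px) for pipeline tests.
smallHeartPhantom <- function(heartRate = 120, duration = 4, noiseSd = 0,
                              seed = 1, frameRate = 35, ...) {
    generateHeartVideo(frameRate = frameRate, duration = duration,
        imageSize = c(96, 96), pixelSize = 1,
        ldD = 70, ldS = 48, sdD = 48, sdS = 34,
        heartRate = heartRate, noiseSd = noiseSd, seed = seed, ...)
}

# Exact points on an ellipse (no pixelation), for algebraic fit checks.
ellipsePoints <- function(cx, cy, semiMaj, semiMin, angleDeg, n = 100) {
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    a <- angleDeg * pi / 180
    cbind(x = cx + semiMaj * cos(th) * cos(a) - semiMin * sin(th) * sin(a),
          y = cy + semiMaj * cos(th) * sin(a) + semiMin * sin(th) * cos(a))
}

# Brute-force heart-rate oracle: every interior local maximum counts as a
# beat (plateau maxima reported at their centre sample); rate from the mean
# inter-peak interval. Independent of the package's prominence/separation-
# gated peak picker.
bruteForcePeaks <- function(values) {
    r <- rle(values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    v <- r$values
    m <- length(v)
    stopifnot(m >= 3L)
    idx <- which(v[2:(m - 1)] > v[1:(m - 2)] & v[2:(m - 1)] > v[3:m]) + 1L
    as.integer(round((starts[idx] + ends[idx]) / 2))
}

bruteForceHR <- function(values, fs) {
    pk <- bruteForcePeaks(values)
    stopifnot(length(pk) >= 2L)
    60 * (length(pk) - 1L) / ((pk[length(pk)] - pk[1L]) / fs)
}

# Dominant period (in samples) of a periodic signal by autocorrelation:
# the lag with maximal ACF beyond the de-correlation shoulder.
autocorrPeriod <- function(x, minLag = 6L) {
    n <- length(x)
    a <- stats::acf(x, lag.max = floor(n / 2), plot = FALSE,
        demean = TRUE)$acf[-1L]
    lags <- seq_along(a)
    cand <- lags[lags >= minLag]
    cand[which.max(a[cand])]
}

# Symmetric Hausdorff distance between a point set and a densely sampled
# true ellipse.
hausdorffToEllipse <- function(pts, cx, cy, semiMaj, semiMin, angleDeg,
                               nSamp = 2000) {
    ref <- ellipsePoints(cx, cy, semiMaj, semiMin, angleDeg, nSamp)
    d2 <- function(a, b) {
        m <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
        sqrt(m)
    }
    m <- d2(pts, ref)
    max(max(apply(m, 1L, min)), max(apply(m, 2L, min)))
}
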