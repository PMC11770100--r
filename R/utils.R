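# Internal helpers shared across modules.

# Evaluate expr with a reproducible RNG state, restoring the caller's state.
.withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

# Otsu threshold for a plain numeric vector on [0, 1] (256 bins).
# EBImage::otsu() only accepts whole images; this is needed for the second
# stage of the two-stage eye threshold, which operates on a pixel subset.
.otsuVec <- function(v, levels = 256L) {
    b <- pmin(pmax(floor(v * (levels - 1L)), 0), levels - 1L)
    h <- tabulate(b + 1L, nbins = levels)
    w <- cumsum(h)
    m <- cumsum(h * (seq_len(levels) - 1L))
    n <- w[levels]
    mt <- m[levels]
    w0 <- w[-levels]
    w1 <- n - w0
    valid <- w0 > 0 & w1 > 0
    mu0 <- m[-levels] / w0
    mu1 <- (mt - m[-levels]) / w1
    sb <- w0 * w1 * (mu0 - mu1)^2
    sb[!valid] <- -Inf
    k <- which.max(sb)                       # threshold between bin k-1 and k
    (k - 0.5) / (levels - 1L)
}

# Local maxima with prominence and minimum-separation gating.
# Returns sorted sample indices. Plateau peaks are reported at their centre.
.findPeaks <- function(x, minProminence = 0, minSeparation = 0L) {
    n <- length(x)
    if (n < 3L)
        return(integer(0L))
    cand <- integer(0L)
    i <- 2L
    while (i < n) {
        if (x[i] > x[i - 1L]) {
            j <- i
            while (j < n && x[j + 1L] == x[j]) j <- j + 1L  # plateau
            if (j < n && x[j + 1L] < x[j]) {
                cand <- c(cand, as.integer(round((i + j) / 2)))
                i <- j + 1L
                next
            }
            i <- j + 1L
        } else {
            i <- i + 1L
        }
    }
    if (!length(cand))
        return(integer(0L))
    prom <- vapply(cand, function(p) {
        lo <- x[p]
        k <- p
        while (k > 1L && x[k - 1L] <= x[p]) {
            k <- k - 1L
            if (x[k] < lo) lo <- x[k]
        }
        leftMin <- if (k > 1L) lo else min(x[seq_len(p)])
        lo <- x[p]
        k <- p
        while (k < n && x[k + 1L] <= x[p]) {
            k <- k + 1L
            if (x[k] < lo) lo <- x[k]
        }
        rightMin <- if (k < n) lo else min(x[p:n])
        x[p] - max(leftMin, rightMin)
    }, numeric(1L))
    keep <- cand[prom >= minProminence]
    if (minSeparation > 0 && length(keep) > 1L) {
        ord <- keep[order(x[keep], decreasing = TRUE)]
        sel <- integer(0L)
        for (p in ord)
            if (!length(sel) || all(abs(sel - p) >= minSeparation))
                sel <- c(sel, p)
        keep <- sort(sel)
    }
    keep
}

# Boolean ellipse mask on an H x W pixel grid (1-based pixel centres).
# angle in degrees from +x toward +y (y runs down the rows).
.ellipseMask <- function(h, w, cx, cy, semiX, semiY, angle = 0) {
    th <- angle * pi / 180
    xs <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
    ys <- matrix(seq_len(h), h, w) - cy
    xr <- xs * cos(th) + ys * sin(th)
    yr <- -xs * sin(th) + ys * cos(th)
    (xr / semiX)^2 + (yr / semiY)^2 <= 1
}

# Clip to the 8-bit range without re-quantising.
.clip255 <- function(x) pmin(pmax(x, 0), 255)

# Validate an (x, y, w, h) pixel rectangle against frame dimensions.
.checkRect <- function(roi, h, w, what = "roi") {
    if (length(roi) != 4L || any(!is.finite(roi)))
        stop("'", what, "' must be numeric (x, y, w, h)", call. = FALSE)
    if (roi[3L] < 1 || roi[4L] < 1)
        stop("'", what, "' must have positive width and height", call. = FALSE)
    if (roi[1L] < 1 || roi[2L] < 1 ||
        roi[1L] + roi[3L] - 1 > w || roi[2L] + roi[4L] - 1 > h)
        stop("'", what, "' (", paste(roi, collapse = ","),
             ") lies outside the ", h, " x ", w, " px frame", call. = FALSE)
    invisible(round(roi))
}
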