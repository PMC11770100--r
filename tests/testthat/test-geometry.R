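# Ventricle segmentation, ellipse fitting, M-mode and cycle detection.

test_that("segmentation centres on the true ellipse, flags blank frames", {
    ph <- generateHeartVideo(duration = 1, heartRate = 120, noiseSd = 0,
        seed = 1)
    edge <- segmentVentricle(getFrame(ph$video, 1))
    expect_lt(max(abs(attr(edge, "centroid") - ph$truth$center)), 1)
    expect_error(segmentVentricle(matrix(128, 50, 50)), "no ventricle")

    noisy <- generateHeartVideo(duration = 1, heartRate = 120, noiseSd = 10,
        seed = 2)
    edgeN <- segmentVentricle(getFrame(noisy$video, 1))
    hd <- hausdorffToEllipse(edgeN, noisy$truth$center[1L],
        noisy$truth$center[2L], noisy$truth$dLong[1L] / 2,
        noisy$truth$dShort[1L] / 2, 0)
    expect_lte(hd, 2)
})

test_that("the direct ellipse fit is exact on noise-free conic points", {
    pts <- ellipsePoints(60, 80, 75, 50, 30, n = 100)
    fit <- fitEllipse(pts, pixelSize = 1)
    expect_equal(longAxis(fit), 150, tolerance = 1e-6)
    expect_equal(shortAxis(fit), 100, tolerance = 1e-6)
    expect_equal(ellipseAngle(fit), 30, tolerance = 1e-6)
    expect_equal(ellipseCenter(fit), c(60, 80), tolerance = 1e-6)
    expect_lt(fit@residual, 1e-9)

    # circle: equal axes, any angle
    circ <- ellipsePoints(40, 40, 50, 50, 0, n = 64)
    fc <- fitEllipse(circ)
    expect_equal(longAxis(fc), 100, tolerance = 1e-6)
    expect_equal(shortAxis(fc), 100, tolerance = 1e-6)

    # pixel size converts to microns
    f2 <- fitEllipse(pts, pixelSize = 2)
    expect_equal(longAxis(f2), 300, tolerance = 1e-6)
    expect_equal(shortAxis(f2), 200, tolerance = 1e-6)

    expect_error(fitEllipse(pts[1:4, ]), "5 points")
    line <- cbind(1:20, 2 * (1:20) + 3)
    expect_error(fitEllipse(line), "collinear")
})

test_that("fitted axes are invariant to ellipse rotation", {
    base <- generateHeartVideo(duration = 1, heartRate = 120, angle = 0,
        noiseSd = 0, seed = 1)
    rot <- generateHeartVideo(duration = 1, heartRate = 120, angle = 35,
        noiseSd = 0, seed = 1)
    f0 <- fitEllipse(segmentVentricle(getFrame(base$video, 1)))
    f35 <- fitEllipse(segmentVentricle(getFrame(rot$video, 1)))
    expect_lt(abs(longAxis(f0) - longAxis(f35)), 1)
    expect_lt(abs(shortAxis(f0) - shortAxis(f35)), 1)
})

test_that("M-mode stacks line profiles and shows the beat period", {
    v <- VideoStack(array(77, dim = c(30, 30, 5)), frameRate = 35)
    mm <- buildMMode(v, c(3, 15, 28, 15))
    expect_true(all(intensityMatrix(mm) == 77))
    expect_equal(nrow(intensityMatrix(mm)), 5L)
    expect_error(buildMMode(v, c(5, 5, 5, 5)), "zero length")
    expect_error(buildMMode(v, c(1, 1, 40, 1)), "outside")

    ph <- generateHeartVideo(duration = 6, heartRate = 150, noiseSd = 0,
        seed = 1)
    cy <- ph$truth$center[2L]
    mm2 <- buildMMode(ph$video, c(10, cy, 183, cy))
    darkWidth <- rowSums(intensityMatrix(mm2) < 120)
    per <- autocorrPeriod(darkWidth)
    expect_lte(abs(per - 60 / 150 * 35), 1)   # 14 frames per beat
})

test_that("axis time series track ground truth within quantisation", {
    ph <- generateHeartVideo(duration = 2, heartRate = 120, noiseSd = 0,
        seed = 1)
    ax <- axisTimeseries(ph$video)
    expect_true(all(ax$ok))
    expect_lte(max(abs(ax$dLong - ph$truth$dLong)), 2)
    expect_lte(max(abs(ax$dShort - ph$truth$dShort)), 2)

    # static ellipse: both series constant within 0.5 um
    fr <- getFrame(ph$video, 1)
    static <- VideoStack(array(fr, dim = c(dim(fr), 8)), frameRate = 35)
    axs <- axisTimeseries(static)
    expect_lt(diff(range(axs$dLong)), 0.5)
    expect_lt(diff(range(axs$dShort)), 0.5)

    blank <- VideoStack(array(128, dim = c(40, 40, 5)), frameRate = 35)
    expect_error(axisTimeseries(blank), "no usable frames")
})

test_that("cycle detection reads ED/ES extrema off the area series", {
    ph <- generateHeartVideo(duration = 4, heartRate = 120, noiseSd = 0,
        ldD = 150, sdD = 100, ldS = 100, sdS = 70, seed = 1)
    cyc <- detectEdEs(ph$truth$dLong, ph$truth$dShort, 35)
    expect_gte(nrow(cyc), 6)
    expect_true(all(abs(cyc$ldD - 150) <= 2))
    expect_true(all(abs(cyc$sdS - 70) <= 2))
    expect_true(all(cyc$eda >= cyc$esa))
    expect_true(all(cyc$edv >= cyc$esv))
    expect_true(all(cyc$fac >= 0 & cyc$fac <= 100))

    expect_error(detectEdEs(rep(150, 100), rep(100, 100), 35), "constant")

    # two interior diastolic maxima delimit exactly one complete cycle
    one <- generateHeartVideo(duration = 1.12, heartRate = 120, seed = 1)
    cyc1 <- detectEdEs(one$truth$dLong, one$truth$dShort, 35,
        minProminence = 0.1)
    expect_equal(nrow(cyc1), 1L)
})
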