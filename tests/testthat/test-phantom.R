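# The synthetic generators: frame bookkeeping, ground-truth identities,
# determinism, and input validation.

test_that("heart phantom produces the requested frames and labels", {
    ph <- generateHeartVideo(heartRate = 150, duration = 10, frameRate = 35,
        imageSize = c(96, 96), ldD = 70, ldS = 48, sdD = 48, sdS = 34,
        seed = 1)
    expect_equal(nFrames(ph$video), 350)
    expect_equal(ph$truth$heartRate, 150)
    expect_equal(length(ph$truth$dLong), 350)
    expect_equal(frameRate(ph$video), 35)
})

test_that("heart phantom ground truth satisfies the formula identities", {
    ph <- generateHeartVideo(duration = 2, heartRate = 120, noiseSd = 0,
        ldD = 150, sdD = 100, ldS = 100, sdS = 70, pixelSize = 1, seed = 1)
    tr <- ph$truth
    expect_equal(tr$eda, 11780.9724509617, tolerance = 1e-12)
    expect_equal(tr$esa, 5497.78714378214, tolerance = 1e-12)
    expect_equal(tr$fac, 100 * (tr$eda - tr$esa) / tr$eda, tolerance = 1e-12)
    expect_equal(tr$fac, 160 / 3, tolerance = 1e-9)
    expect_equal(tr$sv, tr$edv - tr$esv, tolerance = 1e-12)
    expect_equal(tr$co, tr$sv * tr$heartRate, tolerance = 1e-12)
    # per-frame axes oscillate within the stated extremes, peaking at t = 0
    expect_equal(max(tr$dLong), 150)
    expect_equal(tr$dLong[1L], 150)
    expect_true(min(tr$dLong) >= 100 - 1e-9)
    expect_true(all(ph$truth$dShort <= ph$truth$dLong))
})

test_that("same seed gives bit-identical frames; pixels stay in [0, 255]", {
    a <- generateHeartVideo(duration = 1, heartRate = 120, noiseSd = 20,
        imageSize = c(64, 64), ldD = 40, ldS = 28, sdD = 28, sdS = 20,
        seed = 7)
    b <- generateHeartVideo(duration = 1, heartRate = 120, noiseSd = 20,
        imageSize = c(64, 64), ldD = 40, ldS = 28, sdD = 28, sdS = 20,
        seed = 7)
    expect_identical(frames(a$video), frames(b$video))
    expect_gte(min(frames(a$video)), 0)
    expect_lte(max(frames(a$video)), 255)
    c <- generateHeartVideo(duration = 1, heartRate = 120, noiseSd = 20,
        imageSize = c(64, 64), ldD = 40, ldS = 28, sdD = 28, sdS = 20,
        seed = 8)
    expect_false(identical(frames(a$video), frames(c$video)))
})

test_that("heart phantom rejects unsampleable or degenerate requests", {
    expect_error(generateHeartVideo(frameRate = 4, heartRate = 150,
        duration = 5), "fps")
    expect_error(generateHeartVideo(duration = 0.1, heartRate = 100),
        "period")
    expect_error(generateHeartVideo(ldD = 100, ldS = 120), "ldD > ldS")
    expect_error(generateHeartVideo(sdD = 60, sdS = 70), "ldD > ldS")
    expect_error(generateHeartVideo(ldD = 90, sdD = 100, ldS = 60,
        sdS = 70), "long axis")
    expect_error(generateHeartVideo(intensityInside = 300), "\\[0, 255\\]")
})

test_that("larva phantom encodes orientation in the eye-offset sign", {
    lv <- generateLarvaFrame(eyeOffset = 30, bodyAxisAngle = 0, seed = 1)
    expect_true(lv$truth$present)
    expect_equal(lv$truth$orientation, "head_forward")
    # eyes sit 30 px along +x of the body centroid
    expect_equal(mean(lv$truth$eyeCentroids[, "x"]),
        lv$truth$bodyCentroid[1L] + 30)
    expect_equal(mean(lv$truth$eyeCentroids[, "y"]),
        lv$truth$bodyCentroid[2L])
    lv2 <- generateLarvaFrame(eyeOffset = -30, seed = 1)
    expect_equal(lv2$truth$orientation, "tail_forward")
})

test_that("larva phantom handles empty scenes and bounds violations", {
    bg <- generateLarvaFrame(present = FALSE, seed = 2)
    expect_false(bg$truth$present)
    expect_true(all(bg$image == 200))
    expect_error(generateLarvaFrame(imageSize = c(40, 40), bodyLength = 200,
        eyeOffset = 90), "bounds|body length")
    expect_error(generateLarvaFrame(eyeIntensity = 150,
        bodyIntensity = 120), "darker")
    expect_error(generateLarvaFrame(eyeRadius = 0), "positive")
})

test_that("calibration table generator is exact without noise", {
    tab <- generateCalibrationTable(slope = 0.01, intercept = 0,
        concentrations = c(5, 20, 50, 80, 110), noiseSd = 0)
    expect_equal(tab$absorbance, c(0.05, 0.2, 0.5, 0.8, 1.1))
    expect_equal(tab$concentration_uM, c(5, 20, 50, 80, 110))
    expect_error(generateCalibrationTable(concentrations = numeric(0)),
        "empty")
    n1 <- generateCalibrationTable(noiseSd = 0.01, seed = 3)
    n2 <- generateCalibrationTable(noiseSd = 0.01, seed = 3)
    expect_identical(n1, n2)
})

test_that("video TIFF round trip preserves the 8-bit stack", {
    ph <- generateHeartVideo(duration = 1, heartRate = 120, noiseSd = 10,
        imageSize = c(48, 48), ldD = 30, ldS = 22, sdD = 22, sdS = 16,
        seed = 4)
    p <- file.path(tempdir(), "rt.tif")
    writeVideoTIFF(ph$video, p)
    back <- readVideoTIFF(p, frameRate = 35, pixelSize = 1)
    expect_equal(nFrames(back), nFrames(ph$video))
    expect_equal(frames(back), round(frames(ph$video)), tolerance = 1e-8)
    unlink(p)
})
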