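# Detection, eye segmentation, orientation calls and tracking, validated
# against larva phantom ground truth.

test_that("presence detection separates larva frames from empty channels", {
    lv <- generateLarvaFrame(seed = 1)
    det <- detectLarva(lv$image)
    expect_true(det$present)
    bc <- lv$truth$bodyCentroid
    expect_true(det$bbox["x"] <= bc[1L] &&
        bc[1L] <= det$bbox["x"] + det$bbox["w"] - 1)
    expect_true(det$bbox["y"] <= bc[2L] &&
        bc[2L] <= det$bbox["y"] + det$bbox["h"] - 1)

    bg <- generateLarvaFrame(present = FALSE, seed = 1)
    expect_false(detectLarva(bg$image)$present)
    bgNoisy <- generateLarvaFrame(present = FALSE, noiseSd = 10, seed = 2)
    expect_false(detectLarva(bgNoisy$image)$present)

    # an unreachable area gate always reports absence
    expect_false(detectLarva(lv$image,
        minArea = prod(dim(lv$image)) + 1)$present)
    expect_error(detectLarva(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("eye segmentation finds both eyes near ground truth", {
    lv <- generateLarvaFrame(noiseSd = 0, seed = 1)
    eyes <- segmentEyes(lv$image)
    expect_equal(nrow(eyes), 2L)
    gt <- lv$truth$eyeCentroids
    # match each detection to its closest true centre
    d <- sapply(seq_len(2), function(i)
        min(sqrt(colSums((t(gt) - eyes[i, ])^2))))
    expect_lt(max(d), 1)

    noisy <- generateLarvaFrame(noiseSd = 10, seed = 5)
    eyesN <- segmentEyes(noisy$image)
    expect_equal(nrow(eyesN), 2L)
    dN <- sapply(seq_len(2), function(i)
        min(sqrt(colSums((t(noisy$truth$eyeCentroids) - eyesN[i, ])^2))))
    expect_lt(max(dN), 2)

    bg <- generateLarvaFrame(present = FALSE, seed = 1)
    expect_equal(nrow(segmentEyes(bg$image)), 0L)
})

test_that("eye segmentation is invariant to non-saturating brightness offsets", {
    lv <- generateLarvaFrame(noiseSd = 5, seed = 9)
    base <- segmentEyes(lv$image)
    for (off in c(-20, 15, 40)) {
        shifted <- segmentEyes(lv$image + off)
        expect_equal(unclass(shifted)[order(shifted[, "y"]), ],
            unclass(base)[order(base[, "y"]), ], tolerance = 1e-6)
    }
})

test_that("orientation follows the projected eye-vs-body lead rule", {
    body <- c(100, 65)
    eyes <- rbind(c(130, 58), c(130, 72))
    expect_equal(determineOrientation(eyes, body, 0)$orientation,
        "head_forward")
    # mirrored input about the body centroid is exactly antisymmetric
    mEyes <- cbind(2 * body[1L] - eyes[, 1L], eyes[, 2L])
    expect_equal(determineOrientation(mEyes, body, 0)$orientation,
        "tail_forward")
    # dead-band
    expect_equal(determineOrientation(rbind(c(101, 60), c(101, 70)),
        body, 0, epsilon = 2)$orientation, "undetermined")
    # no eyes is a valid undetermined call, not an error
    expect_equal(determineOrientation(matrix(numeric(0), 0, 2),
        body, 0)$orientation, "undetermined")
    expect_error(determineOrientation(eyes, c(NA, 1), 0), "finite")
})

test_that("full-frame orientation calls are antisymmetric under mirroring", {
    for (seed in 1:5) {
        lv <- generateLarvaFrame(eyeOffset = 30, noiseSd = 5, seed = seed)
        call1 <- orientLarva(lv$image)
        expect_equal(call1$orientation, "head_forward")
        # flip about the vertical (axis-normal) line: x -> W + 1 - x
        flipped <- lv$image[, rev(seq_len(ncol(lv$image)))]
        call2 <- orientLarva(flipped)
        expect_equal(call2$orientation, "tail_forward")
    }
})

test_that("implausibly wide eye pairs are called undetermined", {
    lv <- generateLarvaFrame(noiseSd = 0, seed = 3)
    expect_equal(orientLarva(lv$image, maxEyeDistance = 5)$orientation,
        "undetermined")
    expect_equal(orientLarva(lv$image, maxEyeDistance = 50)$orientation,
        "head_forward")
})

test_that("tracking recovers translation and is quiet on static scenes", {
    mk <- function(cx) generateLarvaFrame(bodyCenter = c(cx, 60),
        imageSize = c(120, 260), seed = 1)$image
    xs <- seq(80, 80 + 3 * 19, by = 3)
    moving <- VideoStack(simplify2array(lapply(xs, mk)), frameRate = 30)
    tr <- trackLarva(moving)
    expect_true(all(tr$present))
    inc <- diff(tr$x)
    expect_true(all(abs(inc - 3) <= 1))

    static <- VideoStack(simplify2array(lapply(rep(100, 10), mk)),
        frameRate = 30)
    ts <- trackLarva(static)
    expect_lt(var(ts$x), 1)
    expect_lt(var(ts$y), 1)

    empty <- trackLarva(array(0, dim = c(10, 10, 0)))
    expect_equal(nrow(empty), 0L)
})
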