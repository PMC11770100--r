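# Hand-evaluated reference values for the closed-form cardiac indicators.

test_that("area, volume, FAC, SV and CO reproduce hand evaluations", {
    # pi/4 * 150 * 100 and pi/6 * D_L * D_S^2 / 1e6, evaluated by hand
    expect_equal(ventricleArea(150, 100), 11780.9724509617, tolerance = 1e-12)
    expect_equal(ventricleArea(100, 70), 5497.78714378214, tolerance = 1e-12)
    expect_equal(ventricleVolume(150, 100), 0.785398163397448,
        tolerance = 1e-12)
    expect_equal(ventricleVolume(100, 70), 0.256563400043166,
        tolerance = 1e-12)
    expect_equal(
        fractionalAreaChange(11780.9724509617, 5497.78714378214),
        100 * 8 / 15, tolerance = 1e-12)   # = 53.333...%
    expect_equal(
        strokeVolume(0.785398163397448, 0.256563400043166),
        0.528834763354282, tolerance = 1e-12)
    expect_equal(cardiacOutput(0.528834763354282, 150), 79.3252145031423,
        tolerance = 1e-12)
    expect_equal(cardiacOutput(0.27, 159), 42.93, tolerance = 1e-12)
})

test_that("degenerate and symmetric inputs behave as the formulas force", {
    expect_equal(ventricleArea(0, 123), 0)
    expect_equal(ventricleArea(80, 80), pi * 80^2 / 4)
    expect_equal(ventricleVolume(123, 0), 0)
    expect_equal(fractionalAreaChange(100, 50), 50)
    expect_equal(fractionalAreaChange(77, 77), 0)
    expect_equal(strokeVolume(0.4, 0.4), 0)
    expect_equal(cardiacOutput(0, 200), 0)
})

test_that("mis-ordered extrema are rejected", {
    expect_error(fractionalAreaChange(50, 100), "mis-ordered")
    expect_error(strokeVolume(0.5, 0.6), "mis-ordered")
    expect_error(fractionalAreaChange(0, 0))
})

test_that("formula identities hold to 1e-9 relative on an input grid", {
    dl <- c(30, 75.5, 120, 150, 210.25)
    ds <- c(20, 50.5, 90, 100, 180.75)
    for (i in seq_along(dl)) for (j in seq_along(ds)) {
        if (ds[j] > dl[i]) next
        a <- ventricleArea(dl[i], ds[j])
        v <- ventricleVolume(dl[i], ds[j])
        expect_equal(a, pi / 4 * dl[i] * ds[j], tolerance = 1e-9)
        expect_equal(v, pi / 6 * dl[i] * ds[j]^2 / 1e6, tolerance = 1e-9)
        # contraction to 70% of each axis
        a2 <- ventricleArea(0.7 * dl[i], 0.7 * ds[j])
        v2 <- ventricleVolume(0.7 * dl[i], 0.7 * ds[j])
        expect_equal(fractionalAreaChange(a, a2), 100 * (a - a2) / a,
            tolerance = 1e-9)
        expect_equal(strokeVolume(v, v2), v - v2, tolerance = 1e-9)
        expect_equal(cardiacOutput(v - v2, 137), (v - v2) * 137,
            tolerance = 1e-9)
    }
})

test_that("scaling laws: doubling lengths quadruples areas, octuples volumes", {
    dl <- 150; ds <- 100
    expect_equal(ventricleArea(2 * dl, 2 * ds), 4 * ventricleArea(dl, ds))
    expect_equal(ventricleVolume(2 * dl, 2 * ds),
        8 * ventricleVolume(dl, ds))
    # FAC is scale-invariant
    f1 <- fractionalAreaChange(ventricleArea(dl, ds), ventricleArea(100, 70))
    f2 <- fractionalAreaChange(ventricleArea(2 * dl, 2 * ds),
        ventricleArea(200, 140))
    expect_equal(f1, f2, tolerance = 1e-12)
})
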