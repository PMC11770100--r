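# Dosing maths: mixing solver, gradient plans, Beer--Lambert calibration.

test_that("injection volume solves the mixing relation exactly", {
    v <- injectionVolume(5.56, stock = 110, target = 50)
    expect_equal(v, 50 * 5.56 / 60, tolerance = 1e-12)   # 4.6333 uL
    expect_equal(round(v, 4), 4.6333)
    # forward mixing returns the target exactly
    expect_equal(110 * v / (5.56 + v), 50, tolerance = 1e-12)

    expect_equal(injectionVolume(5.56, 110, 0), 0)
    expect_equal(injectionVolume(5.56, 110, 55), 5.56, tolerance = 1e-12)
    expect_error(injectionVolume(5.56, 110, 110), "unreachable")
    expect_error(injectionVolume(5.56, 110, 150), "unreachable")
})

test_that("forward-mixing identity holds for random valid triples", {
    set.seed(11)
    for (i in 1:200) {
        vd <- runif(1, 0.5, 50)
        st <- runif(1, 1, 1000)
        tg <- runif(1, 0, 0.999) * st
        vi <- injectionVolume(vd, st, tg)
        expect_equal(st * vi / (vd + vi), tg, tolerance = 1e-12)
    }
})

test_that("gradient plans are monotone and reject unreachable targets", {
    plan <- gradientPlan(5.56, 110, seq(10, 100, by = 10))
    expect_equal(nrow(plan), 10L)
    expect_true(all(diff(plan$inject_uL) > 0))
    expect_equal(plan$target_uM, seq(10, 100, by = 10))
    expect_equal(nrow(gradientPlan(5.56, 110, numeric(0))), 0L)
    expect_error(gradientPlan(5.56, 110, c(50, 110)), "unreachable")
})

test_that("calibration fitting is exact on linear data", {
    tab <- generateCalibrationTable(slope = 0.01, intercept = 0.02,
        concentrations = c(5, 20, 50, 80, 110), noiseSd = 0)
    cal <- fitCalibration(tab)
    expect_equal(slope(cal), 0.01, tolerance = 1e-12)
    expect_equal(intercept(cal), 0.02, tolerance = 1e-12)
    expect_equal(rSquared(cal), 1, tolerance = 1e-12)

    expect_error(fitCalibration(tab[1:2, ]), "3 distinct")
    same <- data.frame(concentration_uM = rep(50, 5),
        absorbance = runif(5))
    expect_error(fitCalibration(same), "3 distinct")

    origin <- fitCalibration(tab, throughOrigin = TRUE)
    expect_equal(intercept(origin), 0)
    expect_gt(slope(origin), 0)
})

test_that("a noisy calibration recovers the slope within 3 standard errors", {
    tab <- generateCalibrationTable(slope = 0.01, intercept = 0,
        noiseSd = 0.005, seed = 21)
    cal <- fitCalibration(tab)
    fit <- lm(absorbance ~ concentration_uM, data = tab)
    se <- summary(fit)$coefficients["concentration_uM", "Std. Error"]
    expect_lt(abs(slope(cal) - 0.01), 3 * se)
    expect_equal(slope(cal), unname(coef(fit)[2L]), tolerance = 1e-12)
})

test_that("absorbance inversion is the exact algebraic inverse", {
    cal <- fitCalibration(generateCalibrationTable(slope = 0.01,
        intercept = 0.03))
    expect_equal(absorbanceToConcentration(0.01 * 50 + 0.03, cal), 50,
        tolerance = 1e-12)
    expect_equal(suppressWarnings(absorbanceToConcentration(0.03, cal)), 0,
        tolerance = 1e-12)
    for (cc in c(5, 33.3, 77, 110)) {
        a <- slope(cal) * cc + intercept(cal)
        expect_equal(absorbanceToConcentration(a, cal), cc,
            tolerance = 1e-12)
    }
    expect_warning(absorbanceToConcentration(5, cal), "outside")
})

test_that("calibration tables round-trip through CSV", {
    tab <- generateCalibrationTable(slope = 0.012, noiseSd = 0.002,
        seed = 4)
    p <- file.path(tempdir(), "cal.csv")
    writeCalibrationTable(tab, p)
    back <- readCalibrationTable(p)
    expect_equal(back$concentration_uM, tab$concentration_uM)
    expect_equal(back$absorbance, tab$absorbance, tolerance = 1e-12)
    unlink(p)
})
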