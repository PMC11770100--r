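# Droplet dosing and concentration-verification maths. The droplet is
# assumed drug-free before injection and mixing complete and instantaneous;
# volumes in uL, concentrations in uM, absorbance dimensionless.

#' Injection volume for a target in-droplet concentration
#'
#' Solves the conservation-of-mass mixing relation
#' `target = stock * Vinj / (Vdroplet + Vinj)` for the stock volume to
#' inject into a drug-free droplet:
#' `Vinj = target * Vdroplet / (stock - target)`.
#'
#' @param dropletVolume droplet volume, uL (the encapsulation plug is about
#'   5.56 uL in the reference chip geometry).
#' @param stock stock concentration, uM.
#' @param target desired final concentration, uM; `0 <= target < stock`.
#' @return Injection volume in uL. Mixing the returned volume reproduces
#'   `target` to machine precision.
#' @examples
#' v <- injectionVolume(5.56, stock = 110, target = 50)
#' v
#' 110 * v / (5.56 + v)   # forward mixing check
#' @export
injectionVolume <- function(dropletVolume, stock, target) {
    stopifnot(dropletVolume > 0, stock > 0)
    if (any(target < 0))
        stop("'target' must be non-negative")
    if (any(target >= stock))
        stop(sprintf(
            "target %.4g uM is unreachable by diluting %.4g uM stock",
            max(target), stock))
    target * dropletVolume / (stock - target)
}

#' Injection plan for a concentration gradient series
#'
#' Applies [injectionVolume()] to a vector of target concentrations, e.g.
#' a 10--100 uM dose ladder, rejecting any unreachable target.
#'
#' @inheritParams injectionVolume
#' @param targets vector of final concentrations, uM.
#' @return A data.frame with columns `target_uM` and `inject_uL`; volumes
#'   increase strictly with the target.
#' @examples
#' gradientPlan(5.56, 110, seq(10, 100, by = 10))
#' @export
gradientPlan <- function(dropletVolume, stock, targets) {
    if (!length(targets))
        return(data.frame(target_uM = numeric(0), inject_uL = numeric(0)))
    data.frame(target_uM = targets,
        inject_uL = injectionVolume(dropletVolume, stock, targets))
}

#' Fit a Beer--Lambert calibration line
#'
#' Ordinary least-squares fit of absorbance on concentration,
#' `A = slope * C + intercept`, with `R^2 = 1 - SS_res / SS_tot`. The
#' Beer--Lambert law implies a zero intercept; the free-intercept fit is
#' the default and `throughOrigin = TRUE` gives the constrained
#' alternative (its `R^2` uses the uncorrected total sum of squares, the
#' usual convention for through-origin regression).
#'
#' @param table data.frame with columns `concentration_uM` and
#'   `absorbance`; at least 3 distinct concentrations.
#' @param throughOrigin force the line through the origin.
#' @return A [Calibration-class].
#' @examples
#' tab <- generateCalibrationTable(slope = 0.01, noiseSd = 0)
#' fitCalibration(tab)
#' @export
fitCalibration <- function(table, throughOrigin = FALSE) {
    stopifnot(all(c("concentration_uM", "absorbance") %in% names(table)))
    cc <- table$concentration_uM
    aa <- table$absorbance
    if (length(unique(cc)) < 3L)
        stop("need at least 3 distinct concentrations to calibrate")
    fit <- if (throughOrigin) stats::lm(aa ~ 0 + cc) else stats::lm(aa ~ cc)
    beta <- stats::coef(fit)
    sl <- unname(beta[length(beta)])
    ic <- if (throughOrigin) 0 else unname(beta[1L])
    ssRes <- sum(stats::residuals(fit)^2)
    ssTot <- if (throughOrigin) sum(aa^2) else sum((aa - mean(aa))^2)
    r2 <- 1 - ssRes / ssTot
    if (sl <= 0)
        stop("fitted calibration slope is not positive; check the table")
    Calibration(slope = sl, intercept = ic, rSquared = min(max(r2, 0), 1),
        concRange = range(cc))
}

#' Invert a calibration: absorbance to concentration
#'
#' @param absorbance measured absorbance value(s).
#' @param cal a [Calibration-class].
#' @return Concentration(s) in uM, `(A - intercept) / slope`. A warning is
#'   issued for readings that fall outside the calibrated range.
#' @examples
#' cal <- fitCalibration(generateCalibrationTable(slope = 0.01))
#' absorbanceToConcentration(0.5, cal)
#' @export
absorbanceToConcentration <- function(absorbance, cal) {
    stopifnot(is(cal, "Calibration"))
    conc <- (absorbance - intercept(cal)) / slope(cal)
    rng <- cal@concRange
    if (any(conc < rng[1L] | conc > rng[2L]))
        warning(sprintf(
            "reading outside the calibrated %g-%g uM range: extrapolating",
            rng[1L], rng[2L]))
    conc
}
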