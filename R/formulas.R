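#' Cardiac geometry and output formulas
#'
#' The five closed-form relations that turn fitted ellipse axes into the
#' cardiac function indicators. The ventricle is treated as an ellipse in
#' the image plane (area) and as a prolate ellipsoid rotated about its long
#' axis (volume). Units are fixed package-wide: axis diameters in microns,
#' areas in square microns, volumes in nanolitres (1 nL = 1e6 um^3), heart
#' rate in beats/min and cardiac output in nL/min.
#'
#' * `ventricleArea(dLong, dShort)` = `pi/4 * dLong * dShort` (um^2)
#' * `fractionalAreaChange(eda, esa)` = `100 * (eda - esa) / eda` (%)
#' * `ventricleVolume(dLong, dShort)` = `pi/6 * dLong * dShort^2 / 1e6` (nL)
#' * `strokeVolume(edv, esv)` = `edv - esv` (nL/beat)
#' * `cardiacOutput(sv, hr)` = `sv * hr` (nL/min)
#'
#' @param dLong long-axis diameter, microns.
#' @param dShort short-axis diameter, microns.
#' @param eda,esa end-diastolic / end-systolic area, square microns.
#' @param edv,esv end-diastolic / end-systolic volume, nL.
#' @param sv stroke volume, nL/beat.
#' @param hr heart rate, beats/min.
#' @return A numeric vector (all functions are vectorised).
#' @examples
#' eda <- ventricleArea(150, 100)
#' esa <- ventricleArea(100, 70)
#' fractionalAreaChange(eda, esa)
#' strokeVolume(ventricleVolume(150, 100), ventricleVolume(100, 70))
#' @name cardiac-formulas
NULL

#' @rdname cardiac-formulas
#' @export
ventricleArea <- function(dLong, dShort) {
    stopifnot(all(dLong >= 0), all(dShort >= 0))
    pi / 4 * dLong * dShort
}

#' @rdname cardiac-formulas
#' @export
fractionalAreaChange <- function(eda, esa) {
    stopifnot(all(eda > 0))
    if (any(esa > eda))
        stop("ESA exceeds EDA: end-diastolic/end-systolic areas mis-ordered")
    if (any(esa < 0))
        stop("areas must be non-negative")
    100 * (eda - esa) / eda
}

#' @rdname cardiac-formulas
#' @export
ventricleVolume <- function(dLong, dShort) {
    stopifnot(all(dLong >= 0), all(dShort >= 0))
    pi / 6 * dLong * dShort^2 / 1e6
}

#' @rdname cardiac-formulas
#' @export
strokeVolume <- function(edv, esv) {
    if (any(esv > edv))
        stop("ESV exceeds EDV: end-diastolic/end-systolic volumes mis-ordered")
    edv - esv
}

#' @rdname cardiac-formulas
#' @export
cardiacOutput <- function(sv, hr) {
    stopifnot(all(sv >= 0), all(hr >= 0))
    sv * hr
}
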