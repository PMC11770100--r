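#' Read and write video stacks, ground truth and calibration tables
#'
#' `writeVideoTIFF()` stores a [VideoStack-class] as an 8-bit multi-page
#' grayscale TIFF; `readVideoTIFF()` loads one back. TIFF carries no frame
#' rate or pixel size, so both are supplied by the caller on read (they are
#' acquisition metadata, exactly as in practice). `writeGroundTruth()`
#' serialises a phantom ground-truth list as a JSON sidecar.
#'
#' @param video a [VideoStack-class].
#' @param path file path.
#' @param frameRate frames/s of the stored stack.
#' @param pixelSize microns per pixel of the stored stack.
#' @return `readVideoTIFF()` returns a [VideoStack-class];
#'   `writeVideoTIFF()` and `writeGroundTruth()` return the path invisibly.
#' @examples
#' ph <- generateHeartVideo(duration = 1, heartRate = 120, seed = 1)
#' p <- file.path(tempdir(), "phantom.tif")
#' writeVideoTIFF(ph$video, p)
#' v <- readVideoTIFF(p, frameRate = 35, pixelSize = 1)
#' nFrames(v)
#' @name video-io
NULL

#' @rdname video-io
#' @export
writeVideoTIFF <- function(video, path) {
    stopifnot(is(video, "VideoStack"))
    fr <- frames(video)
    pages <- lapply(seq_len(nFrames(video)),
        function(k) round(fr[, , k]) / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    invisible(path)
}

#' @rdname video-io
#' @export
readVideoTIFF <- function(path, frameRate, pixelSize = 1) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages))
        pages <- list(pages)
    pages <- lapply(pages, function(p) {
        if (length(dim(p)) == 3L)       # collapse RGB(A) to grayscale
            p <- apply(p[, , seq_len(min(3L, dim(p)[3L])), drop = FALSE],
                c(1L, 2L), mean)
        p * 255
    })
    VideoStack(pages, frameRate = frameRate, pixelSize = pixelSize)
}

#' @rdname video-io
#' @param truth a ground-truth list from a phantom generator.
#' @export
writeGroundTruth <- function(truth, path) {
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(path)
}

#' Read and write calibration tables
#'
#' Calibration tables are plain two-column CSV files
#' (`concentration_uM`, `absorbance`).
#'
#' @param table a data.frame with columns `concentration_uM`, `absorbance`.
#' @param path CSV file path.
#' @return `readCalibrationTable()` returns the data.frame;
#'   `writeCalibrationTable()` returns the path invisibly.
#' @seealso [generateCalibrationTable()], [fitCalibration()]
#' @name calibration-io
NULL

#' @rdname calibration-io
#' @export
writeCalibrationTable <- function(table, path) {
    stopifnot(all(c("concentration_uM", "absorbance") %in% names(table)))
    utils::write.csv(table[, c("concentration_uM", "absorbance")], path,
        row.names = FALSE)
    invisible(path)
}

#' @rdname calibration-io
#' @export
readCalibrationTable <- function(path) {
    tab <- utils::read.csv(path)
    if (!all(c("concentration_uM", "absorbance") %in% names(tab)))
        stop("calibration CSV needs columns 'concentration_uM', 'absorbance'")
    tab
}
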