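# Batch orchestration: analyse manifests of videos grouped by condition,
# summarise per group as mean +/- s.e.m., and serialise everything
# deterministically. Hypothesis testing is deliberately out of scope; the
# summaries mirror the descriptive statistics a dose-series figure plots.

#' Read an experiment manifest
#'
#' A manifest is a CSV with columns `path` (video file), `condition`
#' (non-empty group label) and `concentration_uM` (>= 0).
#'
#' @param path manifest CSV path.
#' @return A validated data.frame.
#' @export
readExperimentManifest <- function(path) {
    man <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("path", "condition", "concentration_uM")
    if (!all(need %in% names(man)))
        stop("manifest needs columns: ", paste(need, collapse = ", "))
    if (any(is.na(man$condition) | !nzchar(man$condition)))
        stop("condition labels must be non-empty")
    if (any(man$concentration_uM < 0))
        stop("concentrations must be non-negative")
    man
}

#' Summarise cardiac reports by condition
#'
#' @param reports list of [CardiacReport-class] objects.
#' @param conditions character vector of group labels, parallel to
#'   `reports`.
#' @return A data.frame with one row per condition: `condition`, `n`, and
#'   mean and s.e.m. (`sd / sqrt(n)`) of HR, FAC, SV and CO.
#' @export
summarizeGroups <- function(reports, conditions) {
    stopifnot(length(reports) == length(conditions), length(reports) > 0)
    sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
        else 0
    grab <- function(f) vapply(reports, f, numeric(1L))
    df <- data.frame(condition = conditions, hr = grab(hr), fac = grab(fac),
        sv = grab(sv), co = grab(co))
    out <- do.call(rbind, lapply(split(df, df$condition), function(g)
        data.frame(condition = g$condition[1L], n = nrow(g),
            hr_mean = mean(g$hr), hr_sem = sem(g$hr),
            fac_mean = mean(g$fac), fac_sem = sem(g$fac),
            sv_mean = mean(g$sv), sv_sem = sem(g$sv),
            co_mean = mean(g$co), co_sem = sem(g$co))))
    rownames(out) <- NULL
    out[order(out$condition), , drop = FALSE]
}

#' Run a batch experiment
#'
#' Analyses every video in a manifest with a shared configuration.
#' Individual failures are logged and excluded (skip-and-log policy, so a
#' single corrupt recording does not abort a batch); the run errors only
#' if nothing could be analysed.
#'
#' @param manifest data.frame as from [readExperimentManifest()], or a path
#'   to a manifest CSV.
#' @param frameRate,pixelSize acquisition metadata shared by all videos.
#' @param config named list of arguments forwarded to [analyzeCardiac()]
#'   (e.g. `band`, `roi`).
#' @param seed integer recorded for provenance (the analysis itself is
#'   deterministic).
#' @return A list with `reports` (named list of [CardiacReport-class]),
#'   `conditions` and `concentrations` (parallel to `reports`),
#'   `summaries` (from [summarizeGroups()]), `failures` (named character
#'   vector of error messages) and `config` (the provenance snapshot).
#' @examples
#' \donttest{
#' dir <- tempfile(); dir.create(dir)
#' for (i in 1:2) writeVideoTIFF(generateHeartVideo(duration = 3,
#'     heartRate = 120, imageSize = c(96, 96), ldD = 70, ldS = 48,
#'     sdD = 48, sdS = 34, seed = i)$video,
#'     file.path(dir, paste0("v", i, ".tif")))
#' man <- data.frame(path = file.path(dir, c("v1.tif", "v2.tif")),
#'     condition = "control", concentration_uM = 0)
#' res <- runExperiment(man, frameRate = 35, pixelSize = 1)
#' res$summaries
#' }
#' @export
runExperiment <- function(manifest, frameRate = 35, pixelSize = 1,
                          config = list(), seed = NULL) {
    if (is.character(manifest))
        manifest <- readExperimentManifest(manifest)
    stopifnot(nrow(manifest) > 0)
    reports <- list()
    conditions <- character()
    concentrations <- numeric()
    failures <- character()
    for (i in seq_len(nrow(manifest))) {
        id <- sub("\\.[^.]*$", "", basename(manifest$path[i]))
        rep <- tryCatch({
            video <- readVideoTIFF(manifest$path[i], frameRate, pixelSize)
            do.call(analyzeCardiac, c(list(video = video), config))
        }, error = function(e) e)
        if (inherits(rep, "error")) {
            failures[id] <- conditionMessage(rep)
            message("skipping ", id, ": ", conditionMessage(rep))
        } else {
            reports[[id]] <- rep
            conditions <- c(conditions, manifest$condition[i])
            concentrations <- c(concentrations, manifest$concentration_uM[i])
        }
    }
    if (!length(reports))
        stop("no video could be analysed (", length(failures), " failure(s))")
    list(reports = reports, conditions = conditions,
        concentrations = concentrations,
        summaries = summarizeGroups(reports, conditions),
        failures = failures,
        config = list(frameRate = frameRate, pixelSize = pixelSize,
            analysis = config, seed = seed,
            package = as.character(utils::packageVersion("LarvaScreen"))))
}

.reportToList <- function(report) {
    list(hr = hr(report), fac = fac(report), sv = sv(report),
        co = co(report), nCycles = nrow(cycles(report)),
        qc = as.list(qcFlags(report)), cycles = cycles(report))
}

#' Serialise an experiment run
#'
#' Writes per-video JSON reports, one combined per-cycle CSV, the
#' group-summary CSV and a provenance snapshot (configuration, package
#' version, failure log) with deterministic field and row ordering — the
#' same inputs and configuration always produce byte-identical files, so
#' runs can be diffed.
#'
#' @param results the list returned by [runExperiment()].
#' @param outDir output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
writeReports <- function(results, outDir) {
    if (!length(results$reports))
        stop("nothing to write: the report list is empty")
    dir.create(file.path(outDir, "reports"), recursive = TRUE,
        showWarnings = FALSE)
    ids <- sort(names(results$reports))
    for (id in ids)
        jsonlite::write_json(.reportToList(results$reports[[id]]),
            file.path(outDir, "reports", paste0(id, ".json")),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
    allCycles <- do.call(rbind, lapply(ids, function(id) {
        cbind(video = id, cycle = seq_len(nrow(cycles(results$reports[[id]]))),
            cycles(results$reports[[id]]))
    }))
    utils::write.csv(allCycles, file.path(outDir, "cycles.csv"),
        row.names = FALSE)
    utils::write.csv(results$summaries, file.path(outDir,
        "group_summary.csv"), row.names = FALSE)
    jsonlite::write_json(
        list(config = results$config,
             videos = as.list(stats::setNames(results$conditions,
                 names(results$reports))[ids]),
             failures = as.list(results$failures)),
        file.path(outDir, "run_info.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(outDir)
}
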