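#' End-to-end pipeline configuration
#'
#' Bundles scene, preprocessing, training and reporting settings for
#' \code{\link{runPipeline}}. The preprocessing defaults follow the signal
#' model: a 3x3 multi-temporal filter window, then anomaly interpolation
#' at a 4.5 dB spike threshold -- run after the filter, because on raw
#' speckle the gamma left tail makes genuine flooding dips look like
#' trough anomalies, while after spatial averaging only coherent
#' (weather-scale) single-date deviations remain (see the vignette).
#'
#' @param scene a \code{\link{sceneConfig}} list.
#' @param anomalyRate,anomalyMagnitudeDb atmospheric anomaly injection.
#' @param filterWindowPx multi-temporal filter window (odd, pixels).
#' @param spikeThresholdDb anomaly-interpolation threshold, dB.
#' @param marginDb envelope margin of the threshold extraction, dB.
#' @param nGroundTruth ground-truth points to survey.
#' @param trainFraction fraction of points used for training.
#' @param bins \code{\link{seasonBins}} used to summarize SoS areas.
#' @param districtNames optional district names for tables.
#' @return Named list of settings.
#' @export
pipelineConfig <- function(scene = sceneConfig(grid = c(64, 64)),
                           anomalyRate = 0.05, anomalyMagnitudeDb = 6,
                           filterWindowPx = 3L, spikeThresholdDb = 4.5,
                           marginDb = 0.5, nGroundTruth = 200L,
                           trainFraction = 0.6,
                           bins = seasonBins(
                               early = c("2017-08-09", "2017-09-14"),
                               major = c("2017-09-15", "2017-11-13"),
                               late = c("2017-11-14", "2018-01-12")),
                           districtNames = NULL) {
    list(scene = scene, anomalyRate = anomalyRate,
        anomalyMagnitudeDb = anomalyMagnitudeDb,
        filterWindowPx = filterWindowPx,
        spikeThresholdDb = spikeThresholdDb, marginDb = marginDb,
        nGroundTruth = nGroundTruth, trainFraction = trainFraction,
        bins = bins, districtNames = districtNames)
}

#' Run the simulate-preprocess-classify-validate pipeline
#'
#' Executes the full chain on a simulated scene: scene synthesis,
#' atmospheric anomaly injection, multi-temporal speckle filtering,
#' anomaly interpolation, ground-truth survey and stratified split,
#' threshold extraction from the training rice signatures, rule-based
#' classification, SoS mapping, district/SoS area tables, season-bin
#' sums, and accuracy assessment on the validation points. Every source
#' of randomness derives from \code{seed}, so a rerun with the same
#' config and seed reproduces every output.
#'
#' @param config a \code{\link{pipelineConfig}} list.
#' @param seed integer master seed.
#' @param outdir optional directory; when given, all artifacts (rice map,
#'   SoS map, area tables, accuracy report, manifest) are written there.
#' @return List with the stack, truth, rule parameters, rice map, area
#'   tables, bin sums, accuracy measures, ground truth and a run manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), seed = 1L,
                        outdir = NULL) {
    timings <- c()
    stage <- function(name, expr) {
        t0 <- proc.time()[3L]
        r <- tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                call. = FALSE))
        timings[[name]] <<- round(proc.time()[3L] - t0, 3)
        r
    }

    scene <- stage("simulate", buildScene(config$scene, seed))
    anom <- stage("anomalies", addAtmosphericAnomalies(scene$stack,
        config$anomalyRate, config$anomalyMagnitudeDb, seed + 1L))
    ## spatial averaging must precede temporal despiking: on raw
    ## ENL-scale speckle the heavy left tail of the gamma distribution
    ## makes genuine flooding dips indistinguishable from trough
    ## anomalies, so the interpolator runs on the filtered stack
    filt <- stage("speckle_filter",
        temporalSpeckleFilter(anom$stack, config$filterWindowPx))
    clean <- stage("anomaly_removal",
        interpolateAnomalies(filt, config$spikeThresholdDb))

    gt <- stage("ground_truth",
        makeGroundTruth(scene$truth, config$nGroundTruth, seed + 2L))
    split <- stage("split",
        splitGroundTruth(gt, config$trainFraction, seed + 3L))

    params <- stage("fit_params", {
        tr <- split$train[split$train$label == "rice", , drop = FALSE]
        px <- .pointPixels(tr, dim(classRaster(scene$truth)),
            pixelSpacing(scene$truth))
        v <- sigmaValues(clean)
        sig <- matrix(v, prod(dim(v)[1:2]), dim(v)[3L])[px, , drop = FALSE]
        extractRuleParameters(sig, acqDates(clean), config$marginDb)
    })

    map <- stage("classify", classifyStack(clean, params))
    areas <- stage("areas", districtAreaTable(map, scene$truth,
        districtNames = config$districtNames))
    sosTab <- stage("sos_areas", sosAreaTable(map, scene$truth,
        districtNames = config$districtNames))
    binAreas <- stage("sos_bins", {
        tot <- sosTab[nrow(sosTab), , drop = FALSE]
        cols <- setdiff(names(tot), c("district", "Total"))
        byDate <- data.frame(date = as.Date(cols),
            area_ha = as.numeric(tot[1L, cols]))
        # bins need only cover the dates actually carrying area
        binSosAreas(byDate[byDate$area_ha > 0, , drop = FALSE], config$bins)
    })

    accuracy <- stage("accuracy", {
        nRice <- sum(riceRaster(map) == 1L, na.rm = TRUE)
        if (nRice == 0) NULL else {
            cm <- errorMatrix(map, split$validate)
            list(matrix = cm, overall_pct = overallAccuracy(cm),
                class = producerUserAccuracy(cm),
                kappa = kappaCoefficient(cm))
        }
    })

    manifest <- list(package = "riceSoS",
        version = as.character(utils::packageVersion("riceSoS")),
        seed = seed,
        grid = config$scene$grid,
        parameters = .paramsAsList(params),
        stage_seconds = as.list(timings))

    run <- list(stack = clean, truth = scene$truth, params = params,
        map = map, areas = areas, sosAreas = sosTab, binAreas = binAreas,
        accuracy = accuracy, groundTruth = split, manifest = manifest,
        config = config)
    if (!is.null(outdir)) run$files <- .writeArtifacts(run, outdir)
    run
}

.paramsAsList <- function(params) {
    sl <- methods::slotNames(params)
    x <- lapply(sl, function(s) {
        v <- methods::slot(params, s)
        if (inherits(v, "Date")) format(v) else v
    })
    names(x) <- sl
    x
}

.writeArtifacts <- function(run, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)
    writeByteRaster(riceRaster(run$map), p("rice_map.tif"))
    sos <- sosIndex(run$map)
    writeByteRaster(sos, p("sos_map.tif"))
    rounded <- run$areas
    rounded$area_ha <- round(rounded$area_ha)
    utils::write.csv(rounded, p("district_areas.csv"), row.names = FALSE)
    sosTab <- run$sosAreas
    sosTab[, -1L] <- round(sosTab[, -1L])
    utils::write.csv(sosTab, p("sos_areas.csv"), row.names = FALSE)
    acc <- .accuracyFrame(run$accuracy)
    utils::write.csv(acc, p("accuracy.csv"), row.names = FALSE)
    jsonlite::write_json(run$manifest, p("manifest.json"),
        auto_unbox = TRUE, pretty = TRUE)
    files <- c("rice_map.tif", "sos_map.tif", "district_areas.csv",
        "sos_areas.csv", "accuracy.csv", "manifest.json")
    vapply(files, p, character(1L))
}

.accuracyFrame <- function(accuracy) {
    if (is.null(accuracy))
        return(data.frame(rice_pa_pct = NA, rice_ua_pct = NA,
            overall_accuracy_pct = NA, kappa_index = NA))
    data.frame(
        rice_pa_pct = round(accuracy$class$producer_pct[1L], 1),
        rice_ua_pct = round(accuracy$class$user_pct[1L], 1),
        overall_accuracy_pct = round(accuracy$overall_pct, 1),
        kappa_index = round(accuracy$kappa, 2))
}

#' Write a human-readable run report
#'
#' Emits the district-area, SoS-area, season-bin and accuracy tables as
#' CSV plus a text summary. When the map holds no rice pixels the
#' accuracy section is skipped with a notice.
#'
#' @param run result of \code{\link{runPipeline}}.
#' @param outdir output directory.
#' @return Paths of the written files (invisibly).
#' @export
makeReport <- function(run, outdir) {
    if (is.null(run$areas) || is.null(run$sosAreas))
        stop("missing artifacts: run the pipeline first")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)
    areas <- run$areas
    areas$area_ha <- round(areas$area_ha)
    utils::write.csv(areas, p("report_district_areas.csv"),
        row.names = FALSE)
    bins <- data.frame(bin = names(run$binAreas),
        area_ha = round(as.numeric(run$binAreas)))
    utils::write.csv(bins, p("report_season_bins.csv"), row.names = FALSE)
    utils::write.csv(.accuracyFrame(run$accuracy), p("report_accuracy.csv"),
        row.names = FALSE)

    lines <- c("Rice area and Start-of-Season run summary",
        sprintf("seed: %s   scene: %s pixels", run$manifest$seed,
            paste(run$manifest$grid, collapse = " x ")),
        "",
        "District rice area (ha):",
        sprintf("  %-14s %10.0f", areas$district, areas$area_ha),
        "",
        "SoS season bins (ha):",
        sprintf("  %-6s %10.0f", bins$bin, bins$area_ha),
        "")
    if (is.null(run$accuracy)) {
        lines <- c(lines, "Validation skipped: no rice pixels mapped.")
    } else {
        lines <- c(lines, sprintf(
            "Overall accuracy %.1f%%, kappa %.2f (on %d validation points)",
            run$accuracy$overall_pct, run$accuracy$kappa,
            sum(run$accuracy$matrix)))
    }
    writeLines(lines, p("report_summary.txt"))
    invisible(vapply(c("report_district_areas.csv",
        "report_season_bins.csv", "report_accuracy.csv",
        "report_summary.txt"), p, character(1L)))
}
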