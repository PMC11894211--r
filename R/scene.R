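#' Construct a SarStack
#'
#' @param values H x W x T array of sigma-nought in dB.
#' @param dates acquisition dates (length T).
#' @param nodata optional H x W x T logical mask (default: none).
#' @param pixelSpacing pixel spacing (x, y) in metres.
#' @return A \linkS4class{SarStack}.
#' @export
sarStack <- function(values, dates, nodata = NULL, pixelSpacing = c(10, 10)) {
    if (is.null(nodata))
        nodata <- array(FALSE, dim(values))
    new("SarStack", values = values, dates = as.Date(dates),
        nodata = nodata, pixelSpacing = as.numeric(pixelSpacing))
}

#' Scene simulation configuration
#'
#' Bundles every knob of the synthetic scene generator with defaults that
#' emulate the main (samba, August--January) rice season observed by a
#' 12-day C-band mission: a 14-acquisition calendar starting 9 August,
#' planting dates spread over late September to early November, 10 m
#' pixels, gamma speckle at 4.4 equivalent looks, and a landscape of
#' rectangular fields (rice, other vegetation, permanent water, urban)
#' split into rectangular districts.
#'
#' @param grid scene size c(H, W) in pixels.
#' @param fractions named class fractions (must sum to 1).
#' @param fieldSize side of the square fields, pixels; classes, planting
#'   dates and signature parameters are drawn per field.
#' @param startDate,nAcq,cadenceDays,dropProb calendar settings, see
#'   \code{\link{generateCalendar}}.
#' @param sosDates,sosProbs planting-window distribution of rice SoS dates.
#' @param priors rice dB priors, see \code{\link{riceSignaturePriors}}.
#' @param vegLevelRange,vegAmpRange,waterDb,urbanDb non-rice backbone
#'   levels (dB); stand-ins, configurable.
#' @param noiseSdDb additive dB noise standard deviation.
#' @param speckleLooks equivalent number of looks (Inf = no speckle).
#' @param nDistricts number of vertical district strips.
#' @param pixelSpacing pixel spacing (x, y), metres.
#' @return Named list of settings for \code{\link{buildScene}}.
#' @export
sceneConfig <- function(grid = c(100, 100),
                        fractions = c(rice = 0.6, nonrice_veg = 0.2,
                            water = 0.1, urban = 0.1),
                        fieldSize = 16L,
                        startDate = "2017-08-09", nAcq = 14L,
                        cadenceDays = 12L, dropProb = 0,
                        sosDates = c("2017-09-26", "2017-10-08",
                            "2017-10-20", "2017-11-01"),
                        sosProbs = c(0.2, 0.3, 0.3, 0.2),
                        priors = riceSignaturePriors(),
                        vegLevelRange = c(-13.5, -12.5),
                        vegAmpRange = c(0.6, 1.2),
                        waterDb = -22, urbanDb = -8,
                        noiseSdDb = 0.3, speckleLooks = 4.4,
                        nDistricts = 5L, pixelSpacing = c(10, 10)) {
    list(grid = grid, fractions = fractions, fieldSize = as.integer(fieldSize),
        startDate = startDate, nAcq = nAcq, cadenceDays = cadenceDays,
        dropProb = dropProb, sosDates = as.Date(sosDates),
        sosProbs = sosProbs, priors = priors,
        vegLevelRange = vegLevelRange, vegAmpRange = vegAmpRange,
        waterDb = waterDb, urbanDb = urbanDb, noiseSdDb = noiseSdDb,
        speckleLooks = speckleLooks, nDistricts = as.integer(nDistricts),
        pixelSpacing = pixelSpacing)
}

#' Simulate a SAR scene with known truth
#'
#' Builds a multi-temporal VH sigma-nought stack together with its exact
#' truth. The landscape is a grid of square fields; each field is assigned
#' a class so that per-class pixel counts match the requested fractions
#' exactly (largest-remainder allocation; a handful of fields are split
#' where a class budget runs out). Each rice field receives one signature
#' model drawn from the dB priors and one planting (SoS) date from the
#' planting-window distribution; the recorded SoS truth is the acquisition
#' index nearest the flooding date, which is also the argmin of the
#' noiseless backbone. Additive dB noise and multiplicative gamma speckle
#' are applied per cell.
#'
#' @param config a \code{\link{sceneConfig}} list.
#' @param seed integer seed; the whole scene is a deterministic function of
#'   (config, seed).
#' @return List with elements \code{stack} (\linkS4class{SarStack}) and
#'   \code{truth} (\linkS4class{SceneTruth}).
#' @export
buildScene <- function(config = sceneConfig(), seed = 1L) {
    fr <- config$fractions
    if (abs(sum(fr) - 1) > 1e-8)
        stop("class fractions must sum to 1")
    lv <- c("rice", "nonrice_veg", "water", "urban")
    if (!all(names(fr) %in% lv))
        stop("unknown class in fractions: ",
            paste(setdiff(names(fr), lv), collapse = ", "))
    fr <- fr[lv[lv %in% names(fr)]]
    set.seed(seed)
    H <- config$grid[1L]; W <- config$grid[2L]; N <- H * W
    cal <- generateCalendar(config$startDate, config$nAcq,
        config$cadenceDays, config$dropProb)
    dates <- acqDates(cal)
    T <- length(dates)
    cadence <- .cadenceOf(cal)

    ## --- field grid and exact class allocation -------------------------
    fs <- config$fieldSize
    row <- rep.int(seq_len(H), W)
    col <- rep(seq_len(W), each = H)
    fid <- (ceiling(col / fs) - 1L) * ceiling(H / fs) + ceiling(row / fs)
    fieldPix <- split(seq_len(N), fid)        # column-major pixel ids
    ord <- sample.int(length(fieldPix))       # random field order
    target <- .largestRemainder(fr * N)
    classIdx <- match(names(fr), lv)
    deficit <- target
    classRaster <- integer(N)
    for (f in ord) {
        px <- fieldPix[[f]]
        while (length(px)) {
            k <- which.max(deficit)
            take <- min(deficit[k], length(px))
            classRaster[px[seq_len(take)]] <- classIdx[k]
            deficit[k] <- deficit[k] - take
            px <- px[-seq_len(take)]
        }
    }

    ## --- per-field backbone parameters ---------------------------------
    segs <- split(seq_len(N), list(fid, classRaster), drop = TRUE)
    segClass <- as.integer(sub(".*\\.", "", names(segs)))
    nRiceSeg <- sum(segClass == 1L)
    riceModels <- sampleSignatureModels(max(nRiceSeg, 1L),
        sosDates = config$sosDates, sosProbs = config$sosProbs,
        priors = config$priors)
    vegLevels <- stats::runif(length(segs), config$vegLevelRange[1L],
        config$vegLevelRange[2L])
    vegAmps <- stats::runif(length(segs), config$vegAmpRange[1L],
        config$vegAmpRange[2L])

    values <- matrix(0, N, T)
    sosRaster <- rep(NA_integer_, N)
    iRice <- 0L
    for (s in seq_along(segs)) {
        px <- segs[[s]]
        cls <- segClass[s]
        if (cls == 1L) {
            iRice <- iRice + 1L
            m <- riceModels[iRice, ]
            bb <- .riceBackbone(m$preSeasonDb, m$floodMinDb, m$peakDb,
                m$sosDate, m$riseDays, 0.5, dates, cadence)
            sosRaster[px] <- which.min(bb)
        } else {
            kind <- lv[cls]
            bb <- .nonRiceBackbone(kind,
                switch(kind, nonrice_veg = vegLevels[s],
                    water = config$waterDb, urban = config$urbanDb),
                vegAmps[s], dates)
        }
        values[px, ] <- rep(bb, each = length(px))
    }
    values <- values + .noiseDb(N * T, config$noiseSdDb, config$speckleLooks)

    district <- matrix(pmin(config$nDistricts,
        ceiling(col / (W / config$nDistricts))), H, W)
    truth <- new("SceneTruth",
        classRaster = matrix(classRaster, H, W),
        classLevels = lv,
        sosRaster = matrix(sosRaster, H, W),
        districtRaster = district,
        pixelSpacing = as.numeric(config$pixelSpacing))
    stack <- sarStack(array(values, c(H, W, T)), dates,
        pixelSpacing = config$pixelSpacing)
    list(stack = stack, truth = truth)
}

## Integer allocation matching fractional targets (largest remainder).
.largestRemainder <- function(x) {
    n <- floor(x)
    left <- round(sum(x)) - sum(n)
    if (left > 0) {
        up <- order(x - n, decreasing = TRUE)[seq_len(left)]
        n[up] <- n[up] + 1
    }
    n
}

#' Inject single-acquisition atmospheric anomalies
#'
#' Heavy water vapour or rain at one acquisition shifts sigma-nought up or
#' down for that pass only. A fraction \code{rate} of (pixel, time) cells
#' is perturbed by +/- \code{magnitudeDb} as isolated spikes/troughs: no
#' two consecutive acquisitions of one pixel are ever both flagged, so a
#' 3-point interpolator can repair every anomaly.
#'
#' @param stack a \linkS4class{SarStack}.
#' @param rate fraction of perturbed cells, in [0, 0.2].
#' @param magnitudeDb absolute size of the perturbation, dB (> 0).
#' @param seed optional integer seed.
#' @return List with the perturbed \code{stack} and the logical anomaly
#'   \code{mask} (for oracle testing of the repair step).
#' @export
addAtmosphericAnomalies <- function(stack, rate, magnitudeDb, seed = NULL) {
    if (rate < 0 || rate > 0.2) stop("rate must be in [0, 0.2]")
    if (magnitudeDb <= 0) stop("magnitudeDb must be positive")
    if (!is.null(seed)) set.seed(seed)
    v <- sigmaValues(stack)
    d <- dim(v)
    mask <- array(stats::runif(length(v)) < rate, d)
    for (t in seq_len(d[3L])[-1L])     # enforce isolation in time
        mask[, , t] <- mask[, , t] & !mask[, , t - 1L]
    sign <- ifelse(stats::runif(length(v)) < 0.5, -1, 1)
    v[mask] <- v[mask] + sign[mask] * magnitudeDb
    list(stack = sarStack(v, acqDates(stack), nodataMask(stack),
        pixelSpacing(stack)), mask = mask)
}
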