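#' @import methods
NULL

#' Acquisition calendar of a SAR time series
#'
#' Ordered calendar of satellite passes at a nominal revisit cadence.
#' Individual passes may be missing, so gaps are integer multiples of the
#' cadence (12 days for a single C-band satellite).
#'
#' @slot dates strictly increasing vector of acquisition dates.
#' @slot cadenceDays nominal revisit interval in days.
#' @exportClass AcquisitionCalendar
setClass("AcquisitionCalendar",
    representation(dates = "Date", cadenceDays = "integer"))

setValidity("AcquisitionCalendar", function(object) {
    d <- object@dates
    if (length(d) < 2L)
        return("calendar needs at least 2 acquisition dates")
    if (length(d) > 20L)
        return("calendar longer than 20 acquisitions")
    gaps <- as.numeric(diff(d))
    if (any(gaps <= 0))
        return("dates must be strictly increasing")
    k <- gaps / object@cadenceDays
    if (any(abs(k - round(k)) > 1e-9))
        return("gaps must be integer multiples of cadenceDays")
    TRUE
})

#' Parametric temporal backscatter model of one rice field
#'
#' Piecewise dB backbone of a paddy signature: a pre-season level, a minimum
#' at agronomic flooding (the Start of Season), a monotone rise to the
#' tillering--flowering peak over \code{riseDays}, then a linear decline.
#' Additive Gaussian dB noise and multiplicative gamma speckle (given an
#' equivalent number of looks) are applied on top of the backbone.
#'
#' @slot preSeasonDb dB level before flooding (bare/stubble field).
#' @slot floodMinDb dB at agronomic flooding (the temporal minimum).
#' @slot peakDb dB at the tillering--flowering peak.
#' @slot sosDate calendar date of the flooding minimum.
#' @slot riseDays days from flood minimum to peak.
#' @slot declineDbPerStep post-peak decline per nominal acquisition step, dB.
#' @slot noiseSdDb additive dB noise standard deviation.
#' @slot speckleLooks equivalent number of looks (Inf disables speckle).
#' @exportClass SignatureModel
setClass("SignatureModel",
    representation(preSeasonDb = "numeric", floodMinDb = "numeric",
        peakDb = "numeric", sosDate = "Date", riseDays = "numeric",
        declineDbPerStep = "numeric", noiseSdDb = "numeric",
        speckleLooks = "numeric"))

setValidity("SignatureModel", function(object) {
    if (object@floodMinDb >= object@peakDb)
        return("floodMinDb must be below peakDb")
    if (object@floodMinDb >= object@preSeasonDb)
        return("floodMinDb must be below preSeasonDb")
    if (object@riseDays <= 0) return("riseDays must be positive")
    if (object@noiseSdDb < 0) return("noiseSdDb must be >= 0")
    if (object@speckleLooks <= 0) return("speckleLooks must be positive")
    TRUE
})

#' Multi-temporal sigma-nought stack
#'
#' A T-deep stack of co-registered backscattering-coefficient images in dB,
#' stored as an H x W x T array with its acquisition dates, a nodata mask and
#' the ground pixel spacing in metres.
#'
#' @slot values H x W x T array of sigma-nought in dB.
#' @slot dates acquisition date of each layer.
#' @slot nodata H x W x T logical array, TRUE where no valid observation.
#' @slot pixelSpacing pixel spacing (x, y) in metres; default 10 x 10.
#' @exportClass SarStack
setClass("SarStack",
    representation(values = "array", dates = "Date", nodata = "array",
        pixelSpacing = "numeric"))

setValidity("SarStack", function(object) {
    dv <- dim(object@values)
    if (length(dv) != 3L) return("values must be an H x W x T array")
    if (dv[3L] != length(object@dates))
        return("third dimension must match number of dates")
    if (any(diff(object@dates) <= 0))
        return("dates must be strictly increasing")
    if (!identical(dim(object@nodata), dv))
        return("nodata mask must have the same dimensions as values")
    if (any(!is.finite(object@values[!object@nodata])))
        return("values must be finite where not nodata")
    if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
        return("pixelSpacing must be two positive numbers (metres)")
    TRUE
})

#' Known truth of a simulated scene
#'
#' Per-pixel class labels, true SoS acquisition index (rice pixels only),
#' district labels and pixel spacing for a simulated scene.
#'
#' @slot classRaster H x W integer matrix of class codes indexing
#'   \code{classLevels}.
#' @slot classLevels class names; code 1 is always \code{"rice"}.
#' @slot sosRaster H x W integer matrix of true SoS acquisition indices,
#'   \code{NA} on non-rice pixels.
#' @slot districtRaster H x W integer matrix of district ids (>= 1).
#' @slot pixelSpacing pixel spacing (x, y) in metres.
#' @exportClass SceneTruth
setClass("SceneTruth",
    representation(classRaster = "matrix", classLevels = "character",
        sosRaster = "matrix", districtRaster = "matrix",
        pixelSpacing = "numeric"))

setValidity("SceneTruth", function(object) {
    d <- dim(object@classRaster)
    if (!identical(dim(object@sosRaster), d) ||
        !identical(dim(object@districtRaster), d))
        return("class, SoS and district rasters must share dimensions")
    rice <- object@classRaster == 1L
    if (any(is.na(object@sosRaster[rice])))
        return("sosRaster must be defined on every rice pixel")
    if (any(!is.na(object@sosRaster[!rice])))
        return("sosRaster must be NA off rice pixels")
    if (any(is.na(object@districtRaster)))
        return("district ids must cover all pixels")
    TRUE
})

#' Thresholds of the rule-based rice classifier
#'
#' The knobs of the multi-temporal rule-based rice detector, derived from
#' training-field temporal signatures: dB envelope bounds on the temporal
#' mean (\code{aLowestMeanDb}, \code{bHighestMeanDb}), on the seasonal
#' variation (\code{fMinVariationDb}, \code{cMaxVariationDb}), the maximum
#' value at SoS (\code{dMaxAtSosDb}), the minimum value at the seasonal peak
#' (\code{eMinAtPeakDb}), the maximum time a pixel may stay flooded, the
#' admissible SoS window, growth-phase (SoS to peak) duration bounds,
#' total season-length bounds and the date of the last acquisition.
#'
#' \code{floodDb} is the threshold defining "underwater" for the
#' time-underwater rule; it is set equal to \code{dMaxAtSosDb} when
#' parameters are extracted from training data, but kept as a separate slot
#' so that relaxing the SoS-value bound does not tighten the flooding-
#' duration rule.
#'
#' @slot aLowestMeanDb,bHighestMeanDb bounds on the temporal mean, dB.
#' @slot cMaxVariationDb,fMinVariationDb bounds on max - min variation, dB.
#' @slot dMaxAtSosDb maximum dB value the seasonal minimum may take.
#' @slot eMinAtPeakDb minimum dB value the post-SoS maximum must reach.
#' @slot floodDb flood threshold for the time-underwater rule, dB.
#' @slot underwaterMaxDays maximum allowed consecutive flooded time, days.
#' @slot sosWindow earliest/latest admissible SoS dates.
#' @slot growthDaysMin,growthDaysMax bounds on SoS-to-peak duration, days.
#' @slot seasonDaysMin,seasonDaysMax total season-length bounds, days
#'   (informational; classification ends at the last acquisition, usually
#'   before harvest).
#' @slot tLast date of the last acquisition.
#' @exportClass RuleParameters
setClass("RuleParameters",
    representation(aLowestMeanDb = "numeric", bHighestMeanDb = "numeric",
        cMaxVariationDb = "numeric", dMaxAtSosDb = "numeric",
        eMinAtPeakDb = "numeric", fMinVariationDb = "numeric",
        floodDb = "numeric", underwaterMaxDays = "numeric",
        sosWindow = "Date", growthDaysMin = "numeric",
        growthDaysMax = "numeric", seasonDaysMin = "numeric",
        seasonDaysMax = "numeric", tLast = "Date"))

setValidity("RuleParameters", function(object) {
    if (object@aLowestMeanDb > object@bHighestMeanDb)
        return("a (lowest mean) must not exceed b (highest mean)")
    if (object@fMinVariationDb > object@cMaxVariationDb)
        return("f (minimum variation) must not exceed c (maximum variation)")
    if (object@fMinVariationDb < 0)
        return("f (minimum variation) must be >= 0")
    if (length(object@sosWindow) != 2L ||
        object@sosWindow[1L] > object@sosWindow[2L])
        return("sosWindow must be (earliest, latest)")
    if (object@growthDaysMin > object@growthDaysMax)
        return("growth-duration bounds out of order")
    if (object@seasonDaysMin > object@seasonDaysMax)
        return("season-length bounds out of order")
    if (object@underwaterMaxDays < 0)
        return("underwaterMaxDays must be >= 0")
    TRUE
})

#' Classified rice map with per-pixel Start of Season
#'
#' Output of \code{\link{classifyStack}}: a per-pixel rice/non-rice raster
#' (with \code{NA} for unclassifiable pixels), the SoS acquisition index on
#' rice pixels, and diagnostic counts of how often each rule rejected a
#' pixel.
#'
#' @slot rice H x W integer matrix: 1 rice, 0 non-rice, NA unclassifiable.
#' @slot sosIndex H x W integer matrix of SoS acquisition indices, defined
#'   exactly on rice pixels.
#' @slot dates the acquisition calendar the indices refer to.
#' @slot failCounts named count of pixels rejected by each rule R1..R7.
#' @slot pixelSpacing pixel spacing (x, y) in metres.
#' @exportClass RiceMap
setClass("RiceMap",
    representation(rice = "matrix", sosIndex = "matrix", dates = "Date",
        failCounts = "numeric", pixelSpacing = "numeric"))

setValidity("RiceMap", function(object) {
    if (!identical(dim(object@rice), dim(object@sosIndex)))
        return("rice and sosIndex rasters must share dimensions")
    rice <- !is.na(object@rice) & object@rice == 1L
    if (any(is.na(object@sosIndex[rice])))
        return("sosIndex must be defined on every rice pixel")
    idx <- object@sosIndex[rice]
    if (length(idx) && (min(idx) < 1L || max(idx) > length(object@dates)))
        return("sosIndex outside the acquisition calendar")
    TRUE
})
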