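#' Accessors for the core classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of one of the package classes.
#' @return The corresponding component (see individual methods).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("acqDates", function(x) standardGeneric("acqDates"))
#' @rdname accessors
#' @export
setGeneric("cadenceDays", function(x) standardGeneric("cadenceDays"))
#' @rdname accessors
#' @export
setGeneric("sigmaValues", function(x) standardGeneric("sigmaValues"))
#' @rdname accessors
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))
#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setGeneric("classRaster", function(x) standardGeneric("classRaster"))
#' @rdname accessors
#' @export
setGeneric("classLevels", function(x) standardGeneric("classLevels"))
#' @rdname accessors
#' @export
setGeneric("sosTruth", function(x) standardGeneric("sosTruth"))
#' @rdname accessors
#' @export
setGeneric("districtRaster", function(x) standardGeneric("districtRaster"))
#' @rdname accessors
#' @export
setGeneric("riceRaster", function(x) standardGeneric("riceRaster"))
#' @rdname accessors
#' @export
setGeneric("sosIndex", function(x) standardGeneric("sosIndex"))
#' @rdname accessors
#' @export
setGeneric("failCounts", function(x) standardGeneric("failCounts"))

#' @rdname accessors
#' @export
setMethod("acqDates", "AcquisitionCalendar", function(x) x@dates)
#' @rdname accessors
#' @export
setMethod("cadenceDays", "AcquisitionCalendar", function(x) x@cadenceDays)
#' @rdname accessors
#' @export
setMethod("acqDates", "SarStack", function(x) x@dates)
#' @rdname accessors
#' @export
setMethod("acqDates", "RiceMap", function(x) x@dates)
#' @rdname accessors
#' @export
setMethod("sigmaValues", "SarStack", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("nodataMask", "SarStack", function(x) x@nodata)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "SarStack", function(x) x@pixelSpacing)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "SceneTruth", function(x) x@pixelSpacing)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "RiceMap", function(x) x@pixelSpacing)
#' @rdname accessors
#' @export
setMethod("classRaster", "SceneTruth", function(x) x@classRaster)
#' @rdname accessors
#' @export
setMethod("classLevels", "SceneTruth", function(x) x@classLevels)
#' @rdname accessors
#' @export
setMethod("sosTruth", "SceneTruth", function(x) x@sosRaster)
#' @rdname accessors
#' @export
setMethod("districtRaster", "SceneTruth", function(x) x@districtRaster)
#' @rdname accessors
#' @export
setMethod("riceRaster", "RiceMap", function(x) x@rice)
#' @rdname accessors
#' @export
setMethod("sosIndex", "RiceMap", function(x) x@sosIndex)
#' @rdname accessors
#' @export
setMethod("failCounts", "RiceMap", function(x) x@failCounts)

#' @export
setMethod("length", "AcquisitionCalendar", function(x) length(x@dates))

#' @export
setMethod("dim", "SarStack", function(x) dim(x@values))

setMethod("show", "AcquisitionCalendar", function(object) {
    d <- object@dates
    cat("AcquisitionCalendar:", length(d), "acquisitions,",
        object@cadenceDays, "day cadence\n  ",
        format(d[1L]), "..", format(d[length(d)]), "\n")
})

setMethod("show", "SarStack", function(object) {
    d <- dim(object@values)
    cat(sprintf("SarStack: %d x %d pixels, %d acquisitions (%s .. %s)\n",
        d[1L], d[2L], d[3L], format(object@dates[1L]),
        format(object@dates[d[3L]])))
    cat(sprintf("  sigma0 range %.2f .. %.2f dB, %d nodata cells, %g x %g m pixels\n",
        min(object@values[!object@nodata]),
        max(object@values[!object@nodata]),
        sum(object@nodata), object@pixelSpacing[1L], object@pixelSpacing[2L]))
})

setMethod("show", "SceneTruth", function(object) {
    tab <- table(factor(object@classLevels[object@classRaster],
        levels = object@classLevels))
    cat("SceneTruth:", paste(dim(object@classRaster), collapse = " x "),
        "pixels\n  ")
    cat(paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
        "\n  districts:", length(unique(as.integer(object@districtRaster))),
        "\n")
})

setMethod("show", "RuleParameters", function(object) {
    cat("RuleParameters (dB thresholds from training signatures):\n")
    cat(sprintf("  mean in [a=%.2f, b=%.2f], variation in [f=%.2f, c=%.2f]\n",
        object@aLowestMeanDb, object@bHighestMeanDb,
        object@fMinVariationDb, object@cMaxVariationDb))
    cat(sprintf("  min <= d=%.2f within SoS window %s .. %s; post-SoS max >= e=%.2f\n",
        object@dMaxAtSosDb, format(object@sosWindow[1L]),
        format(object@sosWindow[2L]), object@eMinAtPeakDb))
    cat(sprintf("  underwater (< %.2f dB) <= %g d; growth %g..%g d; last acquisition %s\n",
        object@floodDb, object@underwaterMaxDays, object@growthDaysMin,
        object@growthDaysMax, format(object@tLast)))
})

setMethod("show", "RiceMap", function(object) {
    r <- object@rice
    cat(sprintf("RiceMap: %d x %d pixels; rice %d, non-rice %d, unclassifiable %d\n",
        nrow(r), ncol(r), sum(r == 1L, na.rm = TRUE),
        sum(r == 0L, na.rm = TRUE), sum(is.na(r))))
    fc <- object@failCounts
    cat("  rule rejections:", paste(names(fc), fc, sep = "=", collapse = " "),
        "\n")
})
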