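#' Convert a pixel count to hectares
#'
#' Area uses the ground pixel spacing (default 10 m x 10 m = 0.01 ha per
#' pixel), which tiles the map without overlap -- not the larger
#' resolution cell of the sensor.
#'
#' @param nPixels pixel count (>= 0).
#' @param pixelSpacing pixel spacing (x, y) in metres.
#' @return Hectares.
#' @examples
#' pixelsToHectares(100)          # 1 ha
#' pixelsToHectares(50858100)     # 508,581 ha
#' @export
pixelsToHectares <- function(nPixels, pixelSpacing = c(10, 10)) {
    if (any(pixelSpacing <= 0)) stop("pixel spacing must be positive")
    if (any(nPixels < 0)) stop("pixel counts must be >= 0")
    nPixels * pixelSpacing[1L] * pixelSpacing[2L] / 1e4
}

#' District-level rice area table
#'
#' Counts classified rice pixels per district and converts them to
#' hectares, appending a zone Total row. Unclassifiable pixels are
#' excluded. Hectares are kept at full precision; rounding to whole
#' hectares happens only when tables are written.
#'
#' @param map a \linkS4class{RiceMap} (or a 0/1/NA rice matrix).
#' @param districts H x W integer matrix of district ids, or a
#'   \linkS4class{SceneTruth}.
#' @param pixelSpacing pixel spacing (x, y) metres; taken from \code{map}
#'   when it is a \linkS4class{RiceMap}.
#' @param districtNames optional names, defaults to district_<id>.
#' @return data.frame with columns \code{district}, \code{area_ha}; last
#'   row is the Total.
#' @export
districtAreaTable <- function(map, districts, pixelSpacing = NULL,
                              districtNames = NULL) {
    rice <- if (is(map, "RiceMap")) riceRaster(map) else map
    if (is.null(pixelSpacing))
        pixelSpacing <- if (is(map, "RiceMap")) pixelSpacing(map) else c(10, 10)
    if (is(districts, "SceneTruth")) districts <- districtRaster(districts)
    if (!identical(dim(rice), dim(districts)))
        stop("rice map and district raster shapes differ")
    ids <- sort(unique(as.integer(districts)))
    counts <- vapply(ids, function(i)
        sum(rice == 1L & districts == i, na.rm = TRUE), numeric(1L))
    if (is.null(districtNames)) districtNames <- paste0("district_", ids)
    ha <- pixelsToHectares(counts, pixelSpacing)
    data.frame(district = c(districtNames, "Total"),
        area_ha = c(ha, sum(ha)))
}

#' District x SoS-date rice area table
#'
#' Cross-tabulates rice pixels by district and SoS acquisition date and
#' converts counts to hectares, with Total row and column (the layout of
#' a per-season SoS statistics table). Column totals feed
#' \code{\link{binSosAreas}}; row totals equal the district areas of
#' \code{\link{districtAreaTable}} on the same map.
#'
#' @inheritParams districtAreaTable
#' @return data.frame: first column \code{district}, one column per
#'   acquisition date (ISO name), last column \code{Total}; last row is
#'   the zone Total.
#' @export
sosAreaTable <- function(map, districts, pixelSpacing = NULL,
                         districtNames = NULL) {
    stopifnot(is(map, "RiceMap"))
    if (is.null(pixelSpacing)) pixelSpacing <- pixelSpacing(map)
    if (is(districts, "SceneTruth")) districts <- districtRaster(districts)
    sos <- sosIndex(map)
    if (!identical(dim(sos), dim(districts)))
        stop("rice map and district raster shapes differ")
    dates <- acqDates(map)
    ids <- sort(unique(as.integer(districts)))
    if (is.null(districtNames)) districtNames <- paste0("district_", ids)
    counts <- table(factor(as.integer(districts)[!is.na(sos)], levels = ids),
        factor(sos[!is.na(sos)], levels = seq_along(dates)))
    ha <- pixelsToHectares(unclass(counts), pixelSpacing)
    out <- data.frame(district = districtNames, ha, check.names = FALSE)
    names(out)[-1L] <- format(dates)
    out$Total <- rowSums(ha)
    rbind(out, data.frame(district = "Total",
        t(colSums(out[, -1L, drop = FALSE])), check.names = FALSE))
}
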