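#' Published Cauvery Delta rice statistics shipped with the package
#'
#' Reference area statistics for the Cauvery Delta Zone of Tamil Nadu
#' (districts Thanjavur, Thiruvarur, Nagapattinam, Cuddalore,
#' Tiruchirapalli), samba seasons 2017-18 to 2022-23, derived from
#' operational C-band SAR rice mapping at 12-day cadence:
#' \itemize{
#' \item \code{publishedRiceAreas}: district rice area (ha) per season;
#' \item \code{publishedSosTotals}: zone-wide rice area (ha) per SoS
#'   acquisition date;
#' \item \code{publishedSosDistrictColumns}: district breakdown of the two
#'   largest single-date SoS columns (1 Nov 2017 and 16 Oct 2020);
#' \item \code{publishedSeasonBins}: the early/major/late planting windows
#'   of each season as \code{\link{seasonBins}}.
#' }
#' These tables are the inputs of the desk-scale area-accounting checks;
#' the simulator, not these tables, drives the classifier tests.
#'
#' @param year season key like \code{"2017-18"}; NULL returns all rows.
#' @return data.frame (or \code{\link{seasonBins}} for the bins reader).
#' @export
publishedRiceAreas <- function(year = NULL) {
    df <- utils::read.csv(system.file("extdata", "cauvery_rice_area_ha.csv",
        package = "riceSoS"))
    if (!is.null(year)) df <- df[df$year == year, , drop = FALSE]
    df
}

#' @rdname publishedRiceAreas
#' @export
publishedSosTotals <- function(year = NULL) {
    df <- utils::read.csv(system.file("extdata", "cauvery_sos_totals_ha.csv",
        package = "riceSoS"))
    df$date <- as.Date(df$date)
    if (!is.null(year)) df <- df[df$year == year, , drop = FALSE]
    df
}

#' @rdname publishedRiceAreas
#' @export
publishedSosDistrictColumns <- function(year = NULL) {
    df <- utils::read.csv(system.file("extdata",
        "cauvery_sos_district_columns_ha.csv", package = "riceSoS"))
    df$date <- as.Date(df$date)
    if (!is.null(year)) df <- df[df$year == year, , drop = FALSE]
    df
}

#' @rdname publishedRiceAreas
#' @export
publishedSeasonBins <- function(year) {
    df <- utils::read.csv(system.file("extdata", "cauvery_season_bins.csv",
        package = "riceSoS"))
    df <- df[df$year == year, , drop = FALSE]
    if (!nrow(df)) stop("no season bins for year ", year)
    g <- function(b) c(df$start[df$bin == b], df$end[df$bin == b])
    seasonBins(g("early"), g("major"), g("late"))
}
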