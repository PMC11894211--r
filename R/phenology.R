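#' Detect the Start of Season of one signature
#'
#' The SoS of a rice pixel is the acquisition date of the minimum dB value
#' (agronomic flooding), optionally restricted to a search window; ties go
#' to the earliest date (SoS is the onset event). SoS is reported at
#' acquisition dates only -- the 12-day cadence is the native resolution
#' of the product and no sub-cadence interpolation is attempted.
#'
#' @param series numeric dB signature (NA = nodata).
#' @param calendar acquisition dates.
#' @param window optional c(earliest, latest) dates to search within.
#' @return The SoS date, or \code{NA} if no valid acquisition lies in the
#'   window.
#' @examples
#' d <- seq(as.Date("2017-08-09"), by = 12, length.out = 14)
#' detectSos(c(-14, -14, -20, -15, -14, rep(-14, 9)), d)  # d[3]
#' @export
detectSos <- function(series, calendar, window = NULL) {
    dates <- .calDates(calendar)
    if (length(series) != length(dates))
        stop("series length must match the calendar")
    cand <- !is.na(series)
    if (!is.null(window)) {
        window <- as.Date(window)
        cand <- cand & dates >= window[1L] & dates <= window[2L]
    }
    if (!any(cand)) return(as.Date(NA))
    idx <- which(cand)[which.min(series[cand])]
    dates[idx]
}

#' Season bins for Start-of-Season dates
#'
#' Early / major / late planting windows of one season, given as inclusive
#' date ranges. The windows are per-year inputs (taken from the season's
#' crop calendar), not computed from the data.
#'
#' @param early,major,late each c(start, end) coercible to Date.
#' @return A \code{seasonBins} data.frame (bin, start, end).
#' @export
seasonBins <- function(early, major, late) {
    df <- data.frame(bin = c("early", "major", "late"),
        start = as.Date(c(early[1L], major[1L], late[1L])),
        end = as.Date(c(early[2L], major[2L], late[2L])))
    if (any(df$start > df$end))
        stop("each bin needs start <= end")
    if (df$end[1L] >= df$start[2L] || df$end[2L] >= df$start[3L])
        stop("bins must be ordered and non-overlapping")
    class(df) <- c("seasonBins", "data.frame")
    df
}

#' Sum per-date SoS areas into early/major/late season bins
#'
#' @param areasByDate data.frame with columns \code{date} and
#'   \code{area_ha}, or a named numeric vector (names = dates).
#' @param bins a \code{\link{seasonBins}} object.
#' @return Named numeric c(early, major, late) in hectares; the bin totals
#'   sum to the total area by construction.
#' @export
binSosAreas <- function(areasByDate, bins) {
    if (!is.data.frame(areasByDate))
        areasByDate <- data.frame(date = as.Date(names(areasByDate)),
            area_ha = as.numeric(areasByDate))
    d <- as.Date(areasByDate$date)
    hit <- outer(d, seq_len(nrow(bins)), function(dd, b)
        dd >= bins$start[b] & dd <= bins$end[b])
    orphan <- rowSums(hit) == 0L
    if (any(orphan))
        stop("SoS dates outside all season bins: ",
            paste(format(d[orphan]), collapse = ", "))
    out <- vapply(seq_len(nrow(bins)), function(b)
        sum(areasByDate$area_ha[hit[, b]]), numeric(1L))
    names(out) <- bins$bin
    out
}
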