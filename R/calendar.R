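#' Build an acquisition calendar
#'
#' Generates the nominal acquisition schedule of a single C-band SAR
#' satellite: \code{nAcq} slots spaced \code{cadenceDays} apart starting at
#' \code{startDate}, with each slot after enough remain optionally dropped
#' with probability \code{dropProb} to emulate missing passes. At least 10
#' acquisitions are always kept, since the rule classifier needs that much
#' temporal depth.
#'
#' @param startDate first acquisition date (anything \code{as.Date} takes).
#' @param nAcq number of nominal acquisition slots (10..20).
#' @param cadenceDays revisit interval in days (default 12).
#' @param dropProb per-slot probability of a missing pass, in [0, 0.3).
#' @param seed optional integer seed for reproducible drops.
#' @return An \linkS4class{AcquisitionCalendar}.
#' @examples
#' generateCalendar("2017-08-09", 14)  # 14 passes, 2017-08-09 .. 2018-01-12
#' @export
generateCalendar <- function(startDate, nAcq, cadenceDays = 12L,
                             dropProb = 0, seed = NULL) {
    startDate <- as.Date(startDate)
    if (nAcq < 10L)
        stop("insufficient temporal depth for rule classification (nAcq < 10)")
    if (nAcq > 20L)
        stop("nAcq must be <= 20")
    if (dropProb < 0 || dropProb >= 0.3)
        stop("dropProb must be in [0, 0.3)")
    dates <- startDate + seq(0L, by = as.integer(cadenceDays),
        length.out = nAcq)
    if (dropProb > 0) {
        if (!is.null(seed)) set.seed(seed)
        drop <- which(stats::runif(nAcq) < dropProb)
        if (length(drop) > nAcq - 10L)
            drop <- drop[seq_len(nAcq - 10L)]
        if (length(drop)) dates <- dates[-drop]
    }
    new("AcquisitionCalendar", dates = dates,
        cadenceDays = as.integer(cadenceDays))
}

## Accept either an AcquisitionCalendar or a plain Date vector everywhere.
.calDates <- function(x) {
    if (is(x, "AcquisitionCalendar")) x@dates else as.Date(x)
}

## Nominal step between acquisitions, robust to occasional missing passes.
.cadenceOf <- function(x) {
    if (is(x, "AcquisitionCalendar")) return(as.numeric(x@cadenceDays))
    as.numeric(stats::median(diff(.calDates(x))))
}
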