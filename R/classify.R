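#' Rule-based rice decision for temporal signatures
#'
#' A pixel is rice iff its (valid-acquisition) temporal signature passes
#' all seven rules:
#' \describe{
#' \item{R1}{temporal mean in [a, b];}
#' \item{R2}{seasonal variation (max - min) in [f, c];}
#' \item{R3}{minimum at or below d, dated inside the SoS window;}
#' \item{R4}{post-minimum maximum at least e;}
#' \item{R5}{days from minimum to post-minimum maximum within the
#'   growth-duration bounds;}
#' \item{R6}{consecutive time at or below the flood threshold starting at
#'   the minimum no longer than the maximum time underwater;}
#' \item{R7}{post-minimum maximum dated no later than the last
#'   acquisition.}
#' }
#' Ties in minima/maxima are broken by the earliest date (SoS is the onset
#' event). Pixels with fewer than \code{minValid} valid acquisitions are
#' unclassifiable (\code{NA}): excluded from maps and area sums, and not
#' counted in the rule-rejection log.
#'
#' @param series numeric dB signature (NA = nodata acquisition).
#' @param calendar acquisition dates.
#' @param params a \linkS4class{RuleParameters}.
#' @param minValid minimum number of valid acquisitions (default 10).
#' @return \code{classifyPixel}: list with \code{isRice} (logical, NA if
#'   unclassifiable), \code{sosIndex}, \code{peakIndex} and
#'   \code{failReasons} (character vector of failed rule ids).
#' @export
classifyPixel <- function(series, calendar, params, minValid = 10L) {
    dates <- .calDates(calendar)
    if (length(series) != length(dates))
        stop("series length must match the calendar")
    dec <- .decisionCore(matrix(series, nrow = 1L), dates, params, minValid)
    fails <- colnames(dec$fail)[dec$fail[1L, ]]
    list(isRice = dec$isRice[1L],
        sosIndex = if (isTRUE(dec$isRice[1L])) dec$sosIndex[1L] else NA_integer_,
        peakIndex = if (isTRUE(dec$isRice[1L])) dec$peakIndex[1L] else NA_integer_,
        failReasons = if (isTRUE(is.na(dec$isRice[1L]))) character(0) else fails)
}

#' @rdname classifyPixel
#' @param stack a \linkS4class{SarStack}.
#' @return \code{classifyStack}: a \linkS4class{RiceMap}; pixelwise
#'   identical to applying \code{classifyPixel} independently.
#' @export
classifyStack <- function(stack, params, minValid = 10L) {
    v <- sigmaValues(stack)
    nd <- nodataMask(stack)
    d <- dim(v)
    np <- d[1L] * d[2L]
    m <- matrix(v, np, d[3L])
    m[matrix(nd, np, d[3L])] <- NA
    dec <- .decisionCore(m, acqDates(stack), params, minValid)
    rice <- matrix(as.integer(dec$isRice), d[1L], d[2L])
    sos <- matrix(ifelse(!is.na(dec$isRice) & dec$isRice,
        dec$sosIndex, NA_integer_), d[1L], d[2L])
    ok <- !is.na(dec$isRice)
    new("RiceMap", rice = rice, sosIndex = sos, dates = acqDates(stack),
        failCounts = colSums(dec$fail[ok, , drop = FALSE]),
        pixelSpacing = pixelSpacing(stack))
}

## Vectorized decision engine shared by classifyPixel/classifyStack.
## m: pixels x acquisitions matrix in dB with NA for nodata.
.decisionCore <- function(m, dates, params, minValid = 10L) {
    N <- nrow(m); T <- ncol(m)
    dn <- as.numeric(.calDates(dates))
    cadence <- as.numeric(stats::median(diff(dn)))
    valid <- !is.na(m)
    unclass <- rowSums(valid) < minValid
    mInf <- m; mInf[!valid] <- Inf
    mNinf <- m; mNinf[!valid] <- -Inf
    rows <- seq_len(N)
    argmin <- max.col(-mInf, ties.method = "first")
    vmin <- mInf[cbind(rows, argmin)]
    vmax <- mNinf[cbind(rows, max.col(mNinf, ties.method = "first"))]
    tmean <- rowMeans(m, na.rm = TRUE)
    rng <- vmax - vmin
    cols <- col(m)
    after <- cols >= argmin
    mAfter <- mNinf; mAfter[!after] <- -Inf
    peakIdx <- max.col(mAfter, ties.method = "first")
    vpeak <- mAfter[cbind(rows, peakIdx)]

    ## consecutive run at/below the flood threshold from the minimum,
    ## skipping nodata acquisitions
    stopM <- after & valid & (mInf > params@floodDb)
    anyStop <- rowSums(stopM) > 0
    firstStop <- ifelse(anyStop,
        max.col(stopM * (T + 1L - cols), ties.method = "first"), T + 1L)
    belowM <- after & valid & (mInf <= params@floodDb) & (cols < firstStop)
    anyBelow <- rowSums(belowM) > 0
    endIdx <- max.col(belowM * cols, ties.method = "first")
    runDays <- ifelse(anyBelow, dn[endIdx] - dn[argmin] + cadence, 0)

    win <- as.numeric(params@sosWindow)
    gdays <- dn[peakIdx] - dn[argmin]
    fail <- cbind(
        R1 = !(tmean >= params@aLowestMeanDb & tmean <= params@bHighestMeanDb),
        R2 = !(rng >= params@fMinVariationDb & rng <= params@cMaxVariationDb),
        R3 = !(vmin <= params@dMaxAtSosDb &
               dn[argmin] >= win[1L] & dn[argmin] <= win[2L]),
        R4 = !(vpeak >= params@eMinAtPeakDb),
        R5 = !(gdays >= params@growthDaysMin & gdays <= params@growthDaysMax),
        R6 = !(runDays <= params@underwaterMaxDays),
        R7 = !(dn[peakIdx] <= as.numeric(params@tLast)))
    isRice <- rowSums(fail) == 0L
    isRice[unclass] <- NA
    list(isRice = isRice, sosIndex = argmin, peakIndex = peakIdx,
        fail = fail)
}
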