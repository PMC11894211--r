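#' Decibel / linear power conversion
#'
#' Sigma-nought algebra: averaging is physical only in linear power, while
#' every classifier threshold is quoted in dB. Round trip is exact to
#' floating point.
#'
#' @param xDb backscatter in dB.
#' @param x linear power (> 0).
#' @return Linear power, resp. dB.
#' @examples
#' dbToLinear(-20)        # 0.01
#' linearToDb(dbToLinear(-13.7))
#' @export
dbToLinear <- function(xDb) 10^(xDb / 10)

#' @rdname dbToLinear
#' @export
linearToDb <- function(x) {
    if (any(x <= 0, na.rm = TRUE))
        stop("linear power must be positive")
    10 * log10(x)
}

## NA-aware separable box mean over a matrix (odd k), edge-renormalized.
.boxMean <- function(m, k) {
    if (k == 1L) return(m)
    h <- (k - 1L) %/% 2L
    ok <- !is.na(m)
    m[!ok] <- 0
    sum2 <- .boxSum(t(.boxSum(m, h)), h)
    cnt2 <- .boxSum(t(.boxSum(ok + 0, h)), h)
    t(sum2 / cnt2)
}

## Running sum over rows with half-width h via cumulative sums.
.boxSum <- function(m, h) {
    n <- nrow(m)
    cs <- apply(m, 2L, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)
    up <- pmin(seq_len(n) + h, n)
    lo <- seq_len(n) - h - 1L
    top <- cs[up, , drop = FALSE]
    bot <- rbind(matrix(0, sum(lo < 1L), ncol(m)),
        cs[lo[lo >= 1L], , drop = FALSE])
    top - bot
}

#' Multi-temporal speckle filter
#'
#' Mean-preserving temporal-ratio filter balancing reflectivity between
#' acquisitions: in linear power, the output at date t is the local spatial
#' mean at t scaled per pixel by the ratio of the pixel's temporal mean to
#' the temporal mean of its local spatial means. Speckle is averaged over
#' the spatial window while each pixel's temporal mean power -- the
#' quantity the rule thresholds see through the seasonal envelope -- is
#' preserved exactly.
#'
#' @param stack a \linkS4class{SarStack}.
#' @param windowPx odd spatial window side in pixels (1 = identity).
#' @return The filtered \linkS4class{SarStack}.
#' @export
temporalSpeckleFilter <- function(stack, windowPx = 3L) {
    if (windowPx %% 2L != 1L || windowPx < 1L)
        stop("windowPx must be odd and >= 1")
    v <- sigmaValues(stack)
    d <- dim(v)
    if (windowPx > min(d[1L], d[2L]))
        stop("window larger than grid")
    if (windowPx == 1L) return(stack)
    nd <- nodataMask(stack)
    lin <- dbToLinear(v)
    lin[nd] <- NA
    M <- array(0, d)
    for (t in seq_len(d[3L]))
        M[, , t] <- .boxMean(lin[, , t], windowPx)
    np <- d[1L] * d[2L]
    pixMean <- rowMeans(matrix(lin, np), na.rm = TRUE)
    locMean <- rowMeans(matrix(M, np), na.rm = TRUE)
    out <- M * array(pixMean / locMean, d)
    out <- linearToDb(out)
    out[nd] <- v[nd]
    sarStack(out, acqDates(stack), nd, pixelSpacing(stack))
}

#' Repair single-acquisition anomalies by temporal interpolation
#'
#' Identifies isolated peaks and troughs in each pixel's temporal
#' signature -- interior values that deviate from the mean of their two
#' temporal neighbours by more than \code{spikeThresholdDb} with opposing
#' slopes on either side -- and replaces them by the neighbour average.
#' Detection uses the input values throughout (a single pass), endpoints
#' are never altered, and the repair is idempotent on isolated spikes.
#'
#' @param stack a \linkS4class{SarStack}.
#' @param spikeThresholdDb detection threshold in dB (> 0). The default
#'   3 dB is aggressive; pipelines classifying deep flooding dips should
#'   raise it (see the package vignette).
#' @return The repaired \linkS4class{SarStack}.
#' @export
interpolateAnomalies <- function(stack, spikeThresholdDb = 3) {
    if (spikeThresholdDb <= 0) stop("spikeThresholdDb must be positive")
    v <- sigmaValues(stack)
    T <- dim(v)[3L]
    if (T < 3L) {
        warning("fewer than 3 acquisitions; stack returned unchanged")
        return(stack)
    }
    nd <- nodataMask(stack)
    x <- v
    x[nd] <- NA
    out <- v
    for (t in 2:(T - 1L)) {
        prv <- x[, , t - 1L]; cur <- x[, , t]; nxt <- x[, , t + 1L]
        nb <- (prv + nxt) / 2
        hit <- !is.na(nb) & !is.na(cur) &
            abs(cur - nb) > spikeThresholdDb &
            sign(cur - prv) * sign(nxt - cur) < 0
        sl <- out[, , t]
        sl[hit] <- nb[hit]
        out[, , t] <- sl
    }
    sarStack(out, acqDates(stack), nd, pixelSpacing(stack))
}
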