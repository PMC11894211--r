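#' Derive rule thresholds from training-field signatures
#'
#' Turns a set of training-field dB curves into the thresholds of the
#' rule-based rice detector using a min/max envelope +/- margin policy:
#' \itemize{
#' \item a / b: smallest / largest per-signature temporal mean -/+ margin;
#' \item c / f: largest / smallest per-signature (max - min) +/- margin
#'   (f floored at 0);
#' \item d: largest per-signature minimum + margin (and the flood
#'   threshold for the time-underwater rule);
#' \item e: smallest per-signature seasonal-peak value - margin, where
#'   the seasonal peak is the maximum after the minimum -- the flowering
#'   peak follows flooding, and the pre-season level (often higher than a
#'   weak peak) must not masquerade as it;
#' \item SoS window: range of per-signature argmin dates widened by one
#'   acquisition;
#' \item growth-duration bounds: range of observed argmin-to-argmax days
#'   widened by one acquisition;
#' \item maximum time underwater: longest observed consecutive run at or
#'   below d, plus one acquisition.
#' }
#' Temporal means are taken in dB, the scale on which all thresholds are
#' quoted. Widening the margin only relaxes the extracted thresholds.
#'
#' @param training numeric matrix of training signatures (one row per
#'   field/pixel, one column per acquisition), or a list with elements
#'   \code{signatures} and \code{dates} as returned by
#'   \code{\link{readTrainingSignatures}}.
#' @param calendar acquisition dates (ignored when \code{training} carries
#'   its own).
#' @param marginDb envelope slack in dB (>= 0, default 0.5).
#' @param seasonDaysMin,seasonDaysMax total season-length bounds in days;
#'   not observable from a stack that ends before harvest, so these are
#'   calendar-based defaults (90--160 d for the samba season).
#' @return A \linkS4class{RuleParameters}.
#' @export
extractRuleParameters <- function(training, calendar = NULL, marginDb = 0.5,
                                  seasonDaysMin = 90, seasonDaysMax = 160) {
    if (is.list(training) && !is.null(training$signatures)) {
        calendar <- training$dates
        training <- training$signatures
    }
    training <- as.matrix(training)
    if (nrow(training) < 3L)
        stop("insufficient training fields (need >= 3 signatures)")
    dates <- .calDates(calendar)
    if (ncol(training) != length(dates))
        stop("signature length must match the calendar")
    if (marginDb < 0) stop("marginDb must be >= 0")
    dn <- as.numeric(dates)
    cadence <- .cadenceOf(calendar)

    means <- rowMeans(training)
    mins <- apply(training, 1L, min)
    maxs <- apply(training, 1L, max)
    rngs <- maxs - mins
    argmin <- apply(training, 1L, which.min)
    peakIdx <- vapply(seq_len(nrow(training)), function(i) {
        s <- training[i, ]
        j <- seq_along(s) >= argmin[i]
        which(j)[which.max(s[j])]
    }, integer(1L))
    gdays <- dn[peakIdx] - dn[argmin]
    peaks <- training[cbind(seq_len(nrow(training)), peakIdx)]

    ## vet the monitoring-field curves: a usable rice training signature
    ## must rise from its minimum by at least the smallest documented
    ## seedling-to-flowering increase (2.69 dB); noisy curves whose
    ## minimum is not an agronomic flooding event would otherwise poison
    ## the min/max envelope. If too few pass (e.g. degenerate flat
    ## inputs), fall back to the unscreened envelope with a warning.
    keep <- (peaks - mins) >= 2.69
    if (sum(keep) >= 3L) {
        if (any(!keep))
            message(sum(!keep), " training signature(s) without a 2.69 dB ",
                "post-minimum rise excluded from parameter retrieval")
        means <- means[keep]; mins <- mins[keep]; maxs <- maxs[keep]
        rngs <- rngs[keep]; argmin <- argmin[keep]
        peakIdx <- peakIdx[keep]; gdays <- gdays[keep]
        peaks <- peaks[keep]
        training <- training[keep, , drop = FALSE]
    } else {
        warning("degenerate training set: signatures lack the 2.69 dB ",
            "post-minimum rise; envelope extracted without screening")
    }

    d <- max(mins) + marginDb
    e <- min(peaks) - marginDb
    runs <- vapply(seq_len(nrow(training)), function(i)
        .runBelowDays(training[i, ], dn, d, argmin[i], cadence),
        numeric(1L))
    span <- range(dn)
    win <- c(max(span[1L], dn[min(argmin)] - cadence),
             min(span[2L], dn[max(argmin)] + cadence))
    new("RuleParameters",
        aLowestMeanDb = min(means) - marginDb,
        bHighestMeanDb = max(means) + marginDb,
        cMaxVariationDb = max(rngs) + marginDb,
        dMaxAtSosDb = d,
        eMinAtPeakDb = e,
        fMinVariationDb = max(0, min(rngs) - marginDb),
        floodDb = d,
        underwaterMaxDays = max(runs) + cadence,
        sosWindow = as.Date(win, origin = "1970-01-01"),
        growthDaysMin = max(0, min(gdays) - cadence),
        growthDaysMax = max(gdays) + cadence,
        seasonDaysMin = seasonDaysMin,
        seasonDaysMax = seasonDaysMax,
        tLast = dates[length(dates)])
}

## Days spent in the consecutive run of values <= flood starting at the
## argmin, skipping NA acquisitions; one cadence is charged per flooded
## acquisition, so a single flooded pass counts `cadence` days.
.runBelowDays <- function(s, dn, flood, argmin, cadence) {
    if (is.na(s[argmin]) || s[argmin] > flood) return(0)
    end <- argmin
    for (j in seq_along(s)[-seq_len(argmin)]) {
        if (is.na(s[j])) next
        if (s[j] > flood) break
        end <- j
    }
    dn[end] - dn[argmin] + cadence
}

#' Read / write training signatures as CSV
#'
#' CSV layout: an \code{id} column followed by one column per acquisition
#' date (ISO date column headers, values in dB).
#'
#' @param path file path.
#' @param signatures numeric matrix, one row per training field.
#' @param dates acquisition dates.
#' @param ids optional row ids.
#' @return \code{readTrainingSignatures}: list with \code{signatures},
#'   \code{dates}, \code{ids}.
#' @export
readTrainingSignatures <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    dates <- as.Date(names(df)[-1L])
    sig <- as.matrix(df[, -1L, drop = FALSE])
    dimnames(sig) <- NULL
    list(signatures = sig, dates = dates, ids = df[[1L]])
}

#' @rdname readTrainingSignatures
#' @export
writeTrainingSignatures <- function(signatures, dates, path, ids = NULL) {
    if (is.null(ids)) ids <- seq_len(nrow(signatures))
    df <- data.frame(id = ids, signatures, check.names = FALSE)
    names(df)[-1L] <- format(.calDates(dates))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Serialize rule parameters to a text config
#'
#' Writes/reads a \linkS4class{RuleParameters} as YAML so one season's
#' thresholds can be reused across years.
#'
#' @param params a \linkS4class{RuleParameters}.
#' @param path file path.
#' @return \code{readRuleParameters}: the restored object.
#' @export
writeRuleParameters <- function(params, path) {
    sl <- methods::slotNames(params)
    x <- lapply(sl, function(s) {
        v <- methods::slot(params, s)
        if (inherits(v, "Date")) format(v) else v
    })
    names(x) <- sl
    yaml::write_yaml(x, path)
    invisible(path)
}

#' @rdname writeRuleParameters
#' @export
readRuleParameters <- function(path) {
    x <- yaml::read_yaml(path)
    for (s in c("sosWindow", "tLast")) x[[s]] <- as.Date(unlist(x[[s]]))
    do.call(new, c(list("RuleParameters"), x))
}
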