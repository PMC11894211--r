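#' Construct a rice signature model
#'
#' Convenience constructor for \linkS4class{SignatureModel}. The defaults
#' centre the flood minimum and the flowering peak on the midpoints of the
#' dB ranges observed for transplanted paddy in C-band VH time series
#' (minimum about -22 to -17.7 dB, peak about -16.1 to -14.2 dB, a rise of
#' 2.7-6.7 dB with mean 5.07 dB over roughly two months).
#'
#' @param sosDate date of agronomic flooding (the temporal minimum).
#' @param floodMinDb,peakDb,preSeasonDb backbone dB levels.
#' @param riseDays days from flood minimum to peak.
#' @param declineDbPerStep post-peak decline per nominal acquisition, dB.
#' @param noiseSdDb additive dB noise standard deviation.
#' @param speckleLooks equivalent number of looks (Inf = no speckle).
#' @return A \linkS4class{SignatureModel}.
#' @export
signatureModel <- function(sosDate, floodMinDb = -19.86, peakDb = -14.79,
                           preSeasonDb = -14, riseDays = 60,
                           declineDbPerStep = 0.5, noiseSdDb = 0,
                           speckleLooks = Inf) {
    new("SignatureModel", preSeasonDb = preSeasonDb, floodMinDb = floodMinDb,
        peakDb = peakDb, sosDate = as.Date(sosDate), riseDays = riseDays,
        declineDbPerStep = declineDbPerStep, noiseSdDb = noiseSdDb,
        speckleLooks = speckleLooks)
}

#' Default dB priors of the rice signature sampler
#'
#' The flood minimum is confined to [-22.03, -17.69] dB and the peak to
#' [-16.10, -14.20] dB. The seedling-to-flowering rise is drawn uniformly
#' from [3.40, 6.74] dB: symmetric about the observed mean rise of 5.07 dB
#' while staying inside the observed [2.69, 6.74] dB range (independent
#' uniform draws of the two levels would average only 4.71 dB).
#'
#' @return Named list of prior ranges used by \code{\link{sampleSignatureModels}}.
#' @export
riceSignaturePriors <- function() {
    list(floodMinDb = c(-22.03, -17.69),
         peakDb = c(-16.10, -14.20),
         riseDb = c(3.40, 6.74),
         preSeasonDb = c(-15, -13),
         riseDays = c(48, 72))
}

#' Sample rice signature models from the dB priors
#'
#' Draws \code{n} (flood minimum, rise, pre-season level, rise duration,
#' SoS date) tuples such that every noiseless (minimum, peak) pair lies
#' inside the prior rectangles: the rise is drawn first, then the flood
#' minimum uniformly over the sub-interval for which minimum + rise stays
#' inside the peak range.
#'
#' @param n number of models.
#' @param sosDates candidate flooding dates (quantized to the calendar by
#'   the backbone builder).
#' @param sosProbs sampling weights for \code{sosDates}.
#' @param priors prior ranges, see \code{\link{riceSignaturePriors}}.
#' @param noiseSdDb,speckleLooks noise settings copied into each model.
#' @param seed optional integer seed.
#' @return data.frame with one row per model.
#' @export
sampleSignatureModels <- function(n, sosDates, sosProbs = NULL,
                                  priors = riceSignaturePriors(),
                                  noiseSdDb = 0, speckleLooks = Inf,
                                  seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    sosDates <- as.Date(sosDates)
    if (is.null(sosProbs)) sosProbs <- rep(1, length(sosDates))
    rise <- stats::runif(n, priors$riseDb[1L], priors$riseDb[2L])
    lo <- pmax(priors$floodMinDb[1L], priors$peakDb[1L] - rise)
    hi <- pmin(priors$floodMinDb[2L], priors$peakDb[2L] - rise)
    floodMin <- stats::runif(n, lo, hi)
    data.frame(
        floodMinDb = floodMin,
        peakDb = floodMin + rise,
        preSeasonDb = stats::runif(n, priors$preSeasonDb[1L],
            priors$preSeasonDb[2L]),
        riseDays = stats::runif(n, priors$riseDays[1L], priors$riseDays[2L]),
        sosDate = sample(sosDates, n, replace = TRUE, prob = sosProbs),
        noiseSdDb = noiseSdDb,
        speckleLooks = speckleLooks)
}

## Noiseless piecewise backbone of a rice signature evaluated at the
## acquisition dates; the minimum sits exactly at the acquisition nearest
## the flooding date (earliest on ties). The post-peak decline is floored
## at the senesced-canopy level: dry-down never takes VH below about
## -17.5 dB, and specular reflection off open flood water is always
## darker than any vegetated or senesced state of the same field (>= 2 dB
## here), so the flooding dip stays the unique seasonal minimum of the
## noiseless curve.
.riceBackbone <- function(preSeasonDb, floodMinDb, peakDb, sosDate, riseDays,
                          declineDbPerStep, dates, cadence) {
    t0 <- as.numeric(dates)
    sosIdx <- which.min(abs(t0 - as.numeric(as.Date(sosDate))))
    tStar <- t0[sosIdx]
    ## both the dip and the peak are realized exactly at their nearest
    ## acquisitions: the 12-day calendar is the native resolution of the
    ## product, and the printed dB ranges are observed at that sampling
    riseEff <- max(t0[which.min(abs(t0 - (tStar + riseDays)))] - tStar,
        cadence)
    dt <- t0 - tStar
    ## land soaking/puddling wets the field during the acquisition before
    ## transplanting, so the descent into the flooding minimum is gradual
    puddleDb <- (preSeasonDb + floodMinDb) / 2
    v <- ifelse(dt < -cadence, preSeasonDb,
        ifelse(dt < 0, puddleDb,
        ifelse(dt <= riseEff,
            floodMinDb + (peakDb - floodMinDb) * dt / riseEff,
            pmax(peakDb - declineDbPerStep * (dt - riseEff) / cadence,
                max(floodMinDb + 2, -17.5)))))
    v[sosIdx] <- floodMinDb
    v
}

## dB noise: additive Gaussian plus multiplicative gamma speckle expressed
## in dB (mean-one gamma in linear power with shape = equivalent looks).
.noiseDb <- function(n, noiseSdDb, speckleLooks) {
    e <- if (noiseSdDb > 0) stats::rnorm(n, 0, noiseSdDb) else numeric(n)
    if (is.finite(speckleLooks))
        e <- e + 10 * log10(stats::rgamma(n, shape = speckleLooks,
            rate = speckleLooks))
    e
}

#' Simulate one rice temporal signature
#'
#' Evaluates the piecewise rice backbone of \code{model} at the calendar
#' dates and adds the model's dB noise and gamma speckle. The noiseless
#' backbone has its minimum exactly at the acquisition nearest the
#' flooding date.
#'
#' @param model a \linkS4class{SignatureModel}.
#' @param calendar an \linkS4class{AcquisitionCalendar} or Date vector.
#' @param seed optional integer seed.
#' @return Numeric dB series of one value per acquisition.
#' @export
simulateRiceSignature <- function(model, calendar, seed = NULL) {
    dates <- .calDates(calendar)
    if (model@sosDate < dates[1L] ||
        model@sosDate > dates[length(dates)] - model@riseDays)
        stop("sos_date outside the calendar span minus riseDays")
    if (!is.null(seed)) set.seed(seed)
    v <- .riceBackbone(model@preSeasonDb, model@floodMinDb, model@peakDb,
        model@sosDate, model@riseDays, model@declineDbPerStep, dates,
        .cadenceOf(calendar))
    v + .noiseDb(length(v), model@noiseSdDb, model@speckleLooks)
}

#' Simulate a non-rice temporal signature
#'
#' Negative-class backbones used to exercise the classifier: \code{urban}
#' is a high constant (buildings backscatter strongly all season),
#' \code{water} a low constant (specular reflection, flooded the whole
#' season), and \code{nonrice_veg} a moderate level with a gentle seasonal
#' half-sine whose amplitude stays below the 2.69 dB minimum rise of rice
#' and with no flooding dip. None of these are characterized in C-band VH
#' literature at the precision of the rice envelope, so all levels are
#' configurable stand-ins.
#'
#' @param kind one of \code{"nonrice_veg"}, \code{"water"}, \code{"urban"}.
#' @param calendar an \linkS4class{AcquisitionCalendar} or Date vector.
#' @param levelDb backbone level in dB (defaults: veg -13, water -22,
#'   urban -8).
#' @param seasonalAmpDb amplitude of the vegetation half-sine, dB.
#' @param noiseSdDb,speckleLooks noise settings as for rice.
#' @param seed optional integer seed.
#' @return Numeric dB series of one value per acquisition.
#' @export
simulateNonRiceSignature <- function(kind = c("nonrice_veg", "water", "urban"),
                                     calendar, levelDb = NULL,
                                     seasonalAmpDb = 0.9, noiseSdDb = 0,
                                     speckleLooks = Inf, seed = NULL) {
    kind <- match.arg(kind)
    dates <- .calDates(calendar)
    if (is.null(levelDb))
        levelDb <- switch(kind, nonrice_veg = -13, water = -22, urban = -8)
    if (!is.null(seed)) set.seed(seed)
    v <- .nonRiceBackbone(kind, levelDb, seasonalAmpDb, dates)
    v + .noiseDb(length(v), noiseSdDb, speckleLooks)
}

.nonRiceBackbone <- function(kind, levelDb, seasonalAmpDb, dates) {
    n <- length(dates)
    if (kind == "nonrice_veg") {
        span <- as.numeric(dates[n] - dates[1L])
        frac <- as.numeric(dates - dates[1L]) / span
        levelDb + seasonalAmpDb * sin(pi * frac)
    } else rep(levelDb, n)
}
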