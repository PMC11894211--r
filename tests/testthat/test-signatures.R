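test_that("degenerate flat training collapses the envelope as expected", {
    flat <- matrix(-15, 3, 14)
    expect_warning(p <- extractRuleParameters(flat, demoDates(), 0.5),
        "degenerate")
    expect_equal(p@aLowestMeanDb, -15.5)
    expect_equal(p@bHighestMeanDb, -14.5)
    expect_equal(p@cMaxVariationDb, 0.5)
    expect_equal(p@fMinVariationDb, 0)
})

test_that("extracted thresholds equal brute-force statistics", {
    tr <- noiselessTraining(n = 40, seed = 31)
    margin <- 0.5
    p <- extractRuleParameters(tr$signatures, tr$dates, margin)

    # independent recomputation looping over raw series
    sig <- tr$signatures
    dn <- as.numeric(tr$dates)
    cad <- median(diff(dn))
    mins <- maxs <- means <- rngs <- sosD <- gdays <- peaks <- runs <-
        numeric(nrow(sig))
    for (i in seq_len(nrow(sig))) {
        s <- sig[i, ]
        means[i] <- mean(s)
        mins[i] <- min(s); maxs[i] <- max(s)
        rngs[i] <- maxs[i] - mins[i]
        am <- which.min(s)
        sosD[i] <- dn[am]
        pk <- which(seq_along(s) >= am)[which.max(s[seq_along(s) >= am])]
        gdays[i] <- dn[pk] - dn[am]
        peaks[i] <- s[pk]
    }
    d <- max(mins) + margin
    for (i in seq_len(nrow(sig))) {
        s <- sig[i, ]; am <- which.min(s); end <- am
        for (j in seq_along(s)[-seq_len(am)]) {
            if (s[j] > d) break
            end <- j
        }
        runs[i] <- if (s[am] > d) 0 else dn[end] - dn[am] + cad
    }
    expect_equal(p@aLowestMeanDb, min(means) - margin)
    expect_equal(p@bHighestMeanDb, max(means) + margin)
    expect_equal(p@cMaxVariationDb, max(rngs) + margin)
    expect_equal(p@fMinVariationDb, max(0, min(rngs) - margin))
    expect_equal(p@dMaxAtSosDb, d)
    expect_equal(p@eMinAtPeakDb, min(peaks) - margin)
    expect_equal(as.numeric(p@sosWindow),
        c(min(sosD) - cad, max(sosD) + cad))
    expect_equal(p@growthDaysMin, max(0, min(gdays) - cad))
    expect_equal(p@growthDaysMax, max(gdays) + cad)
    expect_equal(p@underwaterMaxDays, max(runs) + cad)
    expect_equal(p@tLast, tr$dates[length(tr$dates)])
})

test_that("d sits inside the published flooding-minimum band", {
    tr <- noiselessTraining(n = 200, seed = 17)
    p <- extractRuleParameters(tr$signatures, tr$dates, 0.5)
    expect_gte(p@dMaxAtSosDb, -22.03)
    expect_lte(p@dMaxAtSosDb, -17.69 + 0.5)
})

test_that("every training signature satisfies its own extracted rules", {
    tr <- noiselessTraining(n = 30, seed = 53)
    p <- extractRuleParameters(tr$signatures, tr$dates, 0.5)
    for (i in seq_len(nrow(tr$signatures))) {
        dec <- classifyPixel(tr$signatures[i, ], tr$dates, p)
        expect_true(dec$isRice)
    }
})

test_that("widening the margin never declassifies rice", {
    tr <- noiselessTraining(n = 25, seed = 71)
    cal <- demoCalendar()
    set.seed(72)
    test <- noiselessTraining(n = 60, seed = 73)$signatures +
        matrix(rnorm(60 * 14, 0, 0.4), 60)
    prev <- rep(FALSE, nrow(test))
    for (margin in c(0.2, 0.5, 1, 2)) {
        p <- extractRuleParameters(tr$signatures, tr$dates, margin)
        rice <- vapply(seq_len(nrow(test)), function(i)
            isTRUE(classifyPixel(test[i, ], tr$dates, p)$isRice), logical(1))
        expect_true(all(rice[prev]))
        prev <- rice
    }
})

test_that("low-contrast curves are excluded from parameter retrieval", {
    tr <- noiselessTraining(n = 10, seed = 91)
    spoiled <- rbind(tr$signatures, matrix(-17, 1, 14))
    expect_message(p2 <- extractRuleParameters(spoiled, tr$dates, 0.5),
        "excluded")
    p1 <- extractRuleParameters(tr$signatures, tr$dates, 0.5)
    expect_equal(p2@eMinAtPeakDb, p1@eMinAtPeakDb)
    expect_equal(p2@aLowestMeanDb, p1@aLowestMeanDb)
})

test_that("training sets and parameters survive file round trips", {
    tr <- noiselessTraining(n = 5, seed = 3)
    f <- tempfile(fileext = ".csv")
    writeTrainingSignatures(tr$signatures, tr$dates, f)
    back <- readTrainingSignatures(f)
    expect_equal(back$signatures, tr$signatures)
    expect_equal(back$dates, tr$dates)

    p <- extractRuleParameters(tr$signatures, tr$dates)
    fy <- tempfile(fileext = ".yml")
    writeRuleParameters(p, fy)
    p2 <- readRuleParameters(fy)
    for (s in methods::slotNames(p))
        expect_equal(methods::slot(p2, s), methods::slot(p, s))

    expect_error(extractRuleParameters(tr$signatures[1:2, ], tr$dates),
        "insufficient training fields")
})
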