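test_that("prototype signatures classify as their agronomic class", {
    p <- defaultTestParams()
    cal <- demoCalendar()

    rice <- simulateRiceSignature(signatureModel("2017-10-08",
        floodMinDb = -20, peakDb = -15, riseDays = 60), cal)
    dec <- classifyPixel(rice, cal, p)
    expect_true(dec$isRice)
    expect_length(dec$failReasons, 0)
    expect_lt(dec$sosIndex, dec$peakIndex)

    urban <- classifyPixel(rep(-8, 14), cal, p)
    expect_false(urban$isRice)
    expect_true(all(c("R2", "R3") %in% urban$failReasons))

    water <- classifyPixel(rep(-22, 14), cal, p)
    expect_false(water$isRice)
    expect_true(all(c("R4", "R6") %in% water$failReasons))
})

test_that("too few valid acquisitions makes a pixel unclassifiable", {
    p <- defaultTestParams()
    cal <- demoCalendar()
    s <- simulateRiceSignature(signatureModel("2017-10-08"), cal)
    s[1:6] <- NA
    dec <- classifyPixel(s, cal, p)
    expect_true(is.na(dec$isRice))
    expect_length(dec$failReasons, 0)

    v <- array(rep(s, each = 1), c(1, 1, 14))
    nd <- array(FALSE, c(1, 1, 14)); nd[, , 1:6] <- TRUE
    v[nd] <- -9999
    map <- classifyStack(sarStack(v, acqDates(cal), nd), p)
    expect_true(is.na(riceRaster(map)[1, 1]))
})

test_that("stack classification equals the per-pixel loop", {
    sc <- buildScene(tinySceneConfig(), seed = 13)
    p <- defaultTestParams()
    map <- classifyStack(sc$stack, p)
    v <- sigmaValues(sc$stack)
    cal <- acqDates(sc$stack)
    for (r in 1:10) for (cc in 1:10) {
        dec <- classifyPixel(v[r, cc, ], cal, p)
        expect_identical(riceRaster(map)[r, cc], as.integer(dec$isRice))
        if (isTRUE(dec$isRice))
            expect_identical(sosIndex(map)[r, cc], dec$sosIndex)
        else
            expect_true(is.na(sosIndex(map)[r, cc]))
    }
})

test_that("decisions are independent of pixel order", {
    sc <- buildScene(tinySceneConfig(grid = c(8, 12)), seed = 14)
    p <- defaultTestParams()
    v <- sigmaValues(sc$stack)
    perm <- sample(8)
    vp <- v[perm, , , drop = FALSE]
    m1 <- riceRaster(classifyStack(sarStack(v, acqDates(sc$stack)), p))
    m2 <- riceRaster(classifyStack(sarStack(vp, acqDates(sc$stack)), p))
    expect_identical(m2, m1[perm, ])
})

test_that("decisions are invariant to nodata padding", {
    p <- defaultTestParams()
    cal <- demoCalendar()
    sc <- buildScene(tinySceneConfig(), seed = 15)
    v <- sigmaValues(sc$stack)
    d <- dim(v)

    # append two nodata acquisitions and interleave one in the middle
    dates2 <- c(acqDates(cal), max(acqDates(cal)) + c(12, 24))
    v2 <- array(-9999, c(d[1], d[2], d[3] + 2))
    v2[, , seq_len(d[3])] <- v
    nd2 <- array(FALSE, dim(v2)); nd2[, , d[3] + 1:2] <- TRUE
    m1 <- classifyStack(sc$stack, p)
    m2 <- classifyStack(sarStack(v2, dates2, nd2), p)
    expect_identical(riceRaster(m2), riceRaster(m1))
    expect_identical(sosIndex(m2), sosIndex(m1))
    expect_identical(failCounts(m2), failCounts(m1))
})

test_that("relaxing any single threshold never flips rice to non-rice", {
    sc <- buildScene(sceneConfig(grid = c(40, 40), noiseSdDb = 0.4,
        speckleLooks = 10), seed = 16)
    p <- defaultTestParams()
    base <- riceRaster(classifyStack(sc$stack, p))

    relax <- list(
        function(q) { q@aLowestMeanDb <- q@aLowestMeanDb - 2; q },
        function(q) { q@bHighestMeanDb <- q@bHighestMeanDb + 2; q },
        function(q) { q@cMaxVariationDb <- q@cMaxVariationDb + 2; q },
        function(q) { q@fMinVariationDb <- max(0, q@fMinVariationDb - 2); q },
        function(q) { q@dMaxAtSosDb <- q@dMaxAtSosDb + 2; q },
        function(q) { q@eMinAtPeakDb <- q@eMinAtPeakDb - 2; q },
        function(q) { q@sosWindow <- q@sosWindow + c(-24, 24); q },
        function(q) { q@underwaterMaxDays <- q@underwaterMaxDays + 24; q },
        function(q) { q@growthDaysMin <- max(0, q@growthDaysMin - 24)
                      q@growthDaysMax <- q@growthDaysMax + 24; q })
    for (f in relax) {
        wider <- riceRaster(classifyStack(sc$stack, f(p)))
        expect_true(all(wider[base == 1L] == 1L))
    }
})

test_that("noiseless scenes are recovered almost perfectly", {
    cfg <- sceneConfig(grid = c(60, 60), noiseSdDb = 0, speckleLooks = Inf)
    sc <- buildScene(cfg, seed = 18)
    gt <- makeGroundTruth(sc$truth, 150, seed = 19)
    split <- splitGroundTruth(gt, 0.6, seed = 20)
    tr <- split$train[split$train$label == "rice", ]
    px <- riceSoS:::.pointPixels(tr, dim(classRaster(sc$truth)), c(10, 10))
    v <- sigmaValues(sc$stack)
    sig <- matrix(v, 3600, dim(v)[3])[px, ]
    p <- extractRuleParameters(sig, acqDates(sc$stack))
    map <- classifyStack(sc$stack, p)
    agree <- mean((riceRaster(map) == 1L) == (classRaster(sc$truth) == 1L))
    expect_gte(agree, 0.95)
})
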