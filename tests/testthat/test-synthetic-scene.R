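test_that("acquisition calendars follow the 12-day revisit pattern", {
    cal <- generateCalendar("2017-08-09", 14)
    d <- acqDates(cal)
    expect_length(d, 14)
    expect_equal(d[1], as.Date("2017-08-09"))
    expect_equal(d[14], as.Date("2018-01-12"))

    d0 <- as.Date("2020-06-01")
    expect_equal(acqDates(generateCalendar(d0, 10, 12, 0)),
        d0 + seq(0, 108, by = 12))

    a <- generateCalendar(d0, 14, 12, 0.2, seed = 5)
    b <- generateCalendar(d0, 14, 12, 0.2, seed = 5)
    expect_identical(acqDates(a), acqDates(b))
    gaps <- as.numeric(diff(acqDates(a)))
    expect_true(all(gaps %% 12 == 0))
    expect_gte(length(a), 10)

    expect_error(generateCalendar(d0, 9), "temporal depth")
    expect_error(generateCalendar(d0, 14, dropProb = 0.4), "dropProb")
})

test_that("rice signatures dip at the acquisition nearest the flooding date", {
    cal <- demoCalendar()
    m <- signatureModel("2017-10-10")
    s <- simulateRiceSignature(m, cal)
    expect_equal(which.min(s),
        which.min(abs(as.numeric(acqDates(cal) - as.Date("2017-10-10")))))
    expect_equal(min(s), -19.86)

    # rise is monotone up to the peak, then the curve declines
    i0 <- which.min(s)
    ipk <- which.max(s[i0:length(s)]) + i0 - 1L
    expect_true(all(diff(s[i0:ipk]) > 0))

    noisy <- signatureModel("2017-10-10", noiseSdDb = 0.5, speckleLooks = 4.4)
    expect_identical(simulateRiceSignature(noisy, cal, seed = 3),
        simulateRiceSignature(noisy, cal, seed = 3))

    expect_error(simulateRiceSignature(signatureModel("2018-01-10"), cal),
        "sos_date")
})

test_that("sampled signatures respect the published dB envelopes", {
    mods <- sampleSignatureModels(10000, sosDates = "2017-10-08", seed = 1)
    rise <- mods$peakDb - mods$floodMinDb
    expect_lt(abs(mean(rise) - 5.07), 0.2)
    expect_true(all(mods$floodMinDb >= -22.03 & mods$floodMinDb <= -17.69))
    expect_true(all(mods$peakDb >= -16.10 & mods$peakDb <= -14.20))
    expect_true(all(rise >= 2.69 & rise <= 6.74))
})

test_that("non-rice backbones stay outside the rice envelope", {
    cal <- demoCalendar()
    expect_equal(simulateNonRiceSignature("urban", cal), rep(-8, 14))
    expect_equal(simulateNonRiceSignature("water", cal), rep(-22, 14))
    veg <- simulateNonRiceSignature("nonrice_veg", cal)
    expect_lt(max(veg) - min(veg), 2.69)
    expect_error(simulateNonRiceSignature("forest", cal))
})

test_that("simulated scenes honour class fractions, SoS support and seeds", {
    cfg <- sceneConfig()   # 100 x 100, rice fraction 0.6
    sc <- buildScene(cfg, seed = 4)
    cls <- classRaster(sc$truth)
    expect_equal(sum(cls == 1L), 6000, tolerance = 60 / 6000)
    expect_equal(dim(sigmaValues(sc$stack)), c(100L, 100L, 14L))

    sc2 <- buildScene(cfg, seed = 4)
    expect_identical(sigmaValues(sc$stack), sigmaValues(sc2$stack))
    expect_identical(classRaster(sc$truth), classRaster(sc2$truth))

    cfg2 <- sceneConfig(grid = c(40, 40), fieldSize = 8L,
        sosDates = c("2017-10-08", "2017-11-01"), sosProbs = c(0.5, 0.5))
    sc3 <- buildScene(cfg2, seed = 9)
    idx <- sort(unique(na.omit(as.vector(sosTruth(sc3$truth)))))
    d <- acqDates(sc3$stack)
    expect_setequal(format(d[idx]), c("2017-10-08", "2017-11-01"))

    bad <- sceneConfig(fractions = c(rice = 0.5, nonrice_veg = 0.2,
        water = 0.1, urban = 0.1))
    expect_error(buildScene(bad, 1), "sum to 1")
})

test_that("SoS truth is defined exactly on rice pixels and districts cover all", {
    sc <- buildScene(sceneConfig(grid = c(50, 50)), seed = 2)
    cls <- classRaster(sc$truth)
    sos <- sosTruth(sc$truth)
    expect_true(all(!is.na(sos[cls == 1L])))
    expect_true(all(is.na(sos[cls != 1L])))
    expect_false(any(is.na(districtRaster(sc$truth))))
    expect_equal(pixelSpacing(sc$truth), c(10, 10))
})

test_that("atmospheric anomalies are isolated single-date perturbations", {
    sc <- buildScene(sceneConfig(grid = c(30, 30)), seed = 5)

    out0 <- addAtmosphericAnomalies(sc$stack, 0, 6, seed = 1)
    expect_identical(sigmaValues(out0$stack), sigmaValues(sc$stack))
    expect_false(any(out0$mask))

    out <- addAtmosphericAnomalies(sc$stack, 0.05, 6, seed = 1)
    n <- sum(out$mask)
    ncells <- length(out$mask)
    expect_lt(abs(n - 0.05 * ncells), 3 * sqrt(0.05 * 0.95 * ncells))

    # no two consecutive acquisitions flagged at one pixel
    m <- matrix(out$mask, 900, 14)
    expect_false(any(m[, -1] & m[, -14]))

    # perturbed exactly where the mask says, by +/- 6 dB
    dv <- sigmaValues(out$stack) - sigmaValues(sc$stack)
    expect_equal(abs(dv[out$mask]), rep(6, sum(out$mask)))
    expect_true(all(dv[!out$mask] == 0))

    expect_error(addAtmosphericAnomalies(sc$stack, 0.5, 6), "rate")
    expect_error(addAtmosphericAnomalies(sc$stack, 0.05, -1), "magnitude")
})
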