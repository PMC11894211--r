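test_that("dB / linear conversion is an exact inverse pair", {
    expect_equal(dbToLinear(0), 1)
    expect_equal(dbToLinear(-20), 0.01)
    x <- seq(-30, 5, by = 0.37)
    expect_equal(linearToDb(dbToLinear(x)), x, tolerance = 1e-12)
    expect_error(linearToDb(c(0.5, 0)), "positive")
    expect_error(linearToDb(-1), "positive")
})

test_that("multi-temporal filter matches its brute-force definition", {
    set.seed(21)
    H <- 9; W <- 7; T <- 5
    v <- array(rnorm(H * W * T, -15, 2), c(H, W, T))
    st <- sarStack(v, demoDates(T))
    out <- sigmaValues(temporalSpeckleFilter(st, 3))

    lin <- dbToLinear(v)
    M <- array(0, dim(v))
    for (t in seq_len(T)) for (r in seq_len(H)) for (cc in seq_len(W)) {
        rr <- max(1, r - 1):min(H, r + 1)
        ccc <- max(1, cc - 1):min(W, cc + 1)
        M[r, cc, t] <- mean(lin[rr, ccc, t])
    }
    pm <- apply(lin, c(1, 2), mean)
    lm <- apply(M, c(1, 2), mean)
    expect_equal(out, 10 * log10(M * array(pm / lm, dim(v))),
        tolerance = 1e-12)
})

test_that("filtering preserves temporal means and leaves constants alone", {
    cst <- sarStack(array(-17, c(8, 8, 5)), demoDates(5))
    expect_equal(sigmaValues(temporalSpeckleFilter(cst, 3)),
        sigmaValues(cst), tolerance = 1e-12)

    sc <- buildScene(sceneConfig(grid = c(40, 40)), seed = 3)
    for (w in c(1L, 3L, 5L)) {
        f <- temporalSpeckleFilter(sc$stack, w)
        before <- apply(dbToLinear(sigmaValues(sc$stack)), c(1, 2), mean)
        after <- apply(dbToLinear(sigmaValues(f)), c(1, 2), mean)
        expect_lt(max(abs(after - before) / before), 1e-6)
    }
    expect_error(temporalSpeckleFilter(sc$stack, 4), "odd")
    expect_error(temporalSpeckleFilter(sc$stack, 99), "larger than grid")
})

test_that("filtering reduces spatial speckle variance on homogeneous regions", {
    set.seed(7)
    T <- 14; n <- 64
    backbone <- seq(-18, -14, length.out = T)
    lin <- array(rep(dbToLinear(backbone), each = n * n) *
        rgamma(n * n * T, 4.4, 4.4), c(n, n, T))
    st <- sarStack(linearToDb(lin), demoDates(T))
    f <- temporalSpeckleFilter(st, 5)
    vin <- apply(sigmaValues(st), 3, function(s) stats::var(as.vector(s)))
    vout <- apply(sigmaValues(f), 3, function(s) stats::var(as.vector(s)))
    expect_true(all(vin / vout >= 3))
})

test_that("anomaly interpolation repairs isolated spikes and nothing else", {
    d5 <- demoDates(5)
    mono <- sarStack(array(rep(seq(-20, -12, length.out = 5), each = 4),
        c(2, 2, 5)), d5)
    expect_equal(sigmaValues(interpolateAnomalies(mono, 3)),
        sigmaValues(mono))

    spike <- sarStack(array(rep(c(-16, -16, -10, -16, -16), each = 1),
        c(1, 1, 5)), d5)
    rep1 <- interpolateAnomalies(spike, 3)
    expect_equal(as.numeric(sigmaValues(rep1)), rep(-16, 5))
    # idempotent on its own output
    expect_equal(sigmaValues(interpolateAnomalies(rep1, 3)),
        sigmaValues(rep1))

    # endpoints never altered
    ends <- sarStack(array(c(-10, -16, -16, -16, -10), c(1, 1, 5)), d5)
    out <- as.numeric(sigmaValues(interpolateAnomalies(ends, 3)))
    expect_equal(out[c(1, 5)], c(-10, -10))

    short <- sarStack(array(-15, c(2, 2, 2)), demoDates(2))
    expect_warning(out2 <- interpolateAnomalies(short, 3), "unchanged")
    expect_equal(sigmaValues(out2), sigmaValues(short))
})

test_that("repair brings a corrupted stack closer to the clean one", {
    sc <- buildScene(sceneConfig(grid = c(40, 40), noiseSdDb = 0.2,
        speckleLooks = Inf), seed = 6)
    corrupted <- addAtmosphericAnomalies(sc$stack, 0.05, 6, seed = 7)
    repaired <- interpolateAnomalies(corrupted$stack, 3)
    clean <- sigmaValues(sc$stack)
    rmse <- function(x) sqrt(mean((x - clean)^2))
    expect_lt(rmse(sigmaValues(repaired)), rmse(sigmaValues(corrupted$stack)))
})
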