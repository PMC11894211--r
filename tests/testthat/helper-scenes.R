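# Shared fixtures, all generated in code.

demoCalendar <- function(n = 14L) generateCalendar("2017-08-09", n)

demoDates <- function(n = 14L)
    seq(as.Date("2017-08-09"), by = 12L, length.out = n)

# Noiseless rice training set drawn from the default dB priors.
noiselessTraining <- function(n = 50L, seed = 101L) {
    cal <- demoCalendar()
    mods <- sampleSignatureModels(n, sosDates = c("2017-09-26", "2017-10-08",
        "2017-10-20", "2017-11-01"), seed = seed)
    sig <- t(vapply(seq_len(n), function(i)
        simulateRiceSignature(signatureModel(mods$sosDate[i],
            floodMinDb = mods$floodMinDb[i], peakDb = mods$peakDb[i],
            preSeasonDb = mods$preSeasonDb[i], riseDays = mods$riseDays[i]),
            cal), numeric(length(cal))))
    list(signatures = sig, dates = acqDates(cal), models = mods)
}

# Small scene used where pixel-level oracles loop over every pixel.
tinySceneConfig <- function(grid = c(10, 10), ...) {
    sceneConfig(grid = grid, fieldSize = 4L, nDistricts = 2L, ...)
}

# Rule parameters extracted from a clean training set (the package's own
# route to a realistic default parameter set).
defaultTestParams <- function() {
    tr <- noiselessTraining()
    extractRuleParameters(tr$signatures, tr$dates)
}
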