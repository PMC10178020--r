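test_that("simulation is fully reproducible from the seed", {
    p <- simParams(seed = 71)
    a <- simulateGlycopeptide("EEQYNSTYR", c(Hex = 5, HexNAc = 4), 2L, p)
    b <- simulateGlycopeptide("EEQYNSTYR", c(Hex = 5, HexNAc = 4), 2L, p)
    expect_identical(peaks(a$spectrum), peaks(b$spectrum))

    na <- simulateNonglyco("AGFAGDDAPR", 2L, p)
    nb <- simulateNonglyco("AGFAGDDAPR", 2L, p)
    expect_identical(peaks(na$spectrum), peaks(nb$spectrum))

    d <- withr::local_tempdir()
    c1 <- simulateCohort(5, 5, params = p,
                         outPrefix = file.path(d, "a"))
    c2 <- simulateCohort(5, 5, params = p,
                         outPrefix = file.path(d, "b"))
    expect_identical(readLines(c1$truthPath)[-1],
                     readLines(c2$truthPath)[-1])
    expect_length(readSpectra(c1$spectraPath), 10)
})

test_that("emitted peak classes reflect the glycan composition", {
    clean <- simParams(ladderCompleteness = 1, byCoverage = 1,
                       nNoisePeaks = 0, seed = 72)
    # no NeuAc in the composition: no sialic-acid oxonium ions
    sim <- simulateGlycopeptide("EEQYNSTYR", c(Hex = 5, HexNAc = 2), 2L,
                                clean)
    mz <- peaks(sim$spectrum)$mz
    expect_false(any(abs(mz - 292.102693) <= 0.02))
    expect_false(any(abs(mz - 274.092128) <= 0.02))
    expect_false(any(abs(mz - 657.234889) <= 0.02))
    expect_true(any(abs(mz - 204.0867) <= 0.02))
    expect_true(any(abs(mz - 366.139472) <= 0.02))

    # the full ladder is present at its true positions
    for (off in patternTemplate())
        expect_true(any(abs(mz - (sim$truth$trueY1Mz + off)) <= 1e-6))

    # compositions outside the generator bounds are rejected
    expect_error(simulateGlycopeptide("EEQYNSTYR", c(Hex = 20), 2L, clean),
                 "bounds")
})

test_that("truth masses are self-consistent with the precursor", {
    set.seed(73)
    pools <- simulationPools()
    for (i in 1:10) {
        sim <- simulateGlycopeptide(
            pools$glycoPeptides[(i %% 8) + 1],
            pools$compositions[[(i %% 10) + 1]],
            charge = 2L + i %% 2, params = simParams(seed = 700 + i))
        expect_equal(sim$truth$trueY1Mz - protonMass() - 203.07937 +
                         sim$truth$trueGlycanMass,
                     precursorNeutralMass(sim$spectrum),
                     tolerance = 1e-9)
        expect_equal(sim$truth$trueGlycanMass,
                     glycanMass(sim$truth$composition), tolerance = 1e-12)
    }
})

test_that("clean deterministic input decomposes perfectly end to end", {
    clean <- simParams(ladderCompleteness = 1, byCoverage = 1,
                       nNoisePeaks = 0, seed = 74)
    sim <- simulateGlycopeptide("VSNQTLSLFFTVLQDVPVR",
                                c(Hex = 6, HexNAc = 5, NeuAc = 3), 3L,
                                clean)
    res <- decomposeSpectrum(sim$spectrum)
    expect_equal(res$outcome, "decomposed")
    top <- patternMatch(res$pair)
    expect_equal(nMatched(top), 8L)
    expect_lt(abs(peptideMoietyMass(top) -
                  peptideNeutralMass("VSNQTLSLFFTVLQDVPVR")), 0.02)
})

test_that("non-glyco spectra are clean negatives with the expected ions", {
    full <- simParams(byCoverage = 1, nNoisePeaks = 0, seed = 75)
    pep <- "DSYVGDEAQSK"
    neg <- simulateNonglyco(pep, 2L, full)
    expect_equal(peakCount(neg$spectrum), 2L * (nchar(pep) - 1L))
    expect_equal(neg$truth$label, "non-glyco")
    f <- prefilterPeaks(neg$spectrum)
    expect_false(classifyGlyco(detectOxonium(f)))
    # no peak anywhere near the oxonium windows, by construction
    for (i in 1:10) {
        neg <- simulateNonglyco("IWHHTFYNELR", 2L,
                                simParams(seed = 800 + i))
        mz <- peaks(neg$spectrum)$mz
        for (o in oxoniumTable()$mz)
            expect_false(any(abs(mz - o) <= 0.02))
    }
})

test_that("cohorts carry labels that the pipeline reproduces when clean", {
    clean <- simParams(ladderCompleteness = 1, byCoverage = 1,
                       nNoisePeaks = 0, seed = 76)
    cohort <- simulateCohort(15, 15, params = clean)
    expect_equal(nrow(cohort$truth), 30)
    st <- decomposeStream(cohort$spectra)
    expect_equal(unname(st$counts[c("decomposed", "non-glyco")]),
                 c(15L, 15L))
    # recovered peptide moiety masses match the truth table
    for (r in st$results) {
        if (r$outcome != "decomposed") next
        tr <- cohort$truth[cohort$truth$id == r$id, ]
        m <- patternMatch(r$pair)
        expect_lt(abs((referenceMz(m)) - tr$trueY1Mz), 0.02)
        expect_lt(abs(glycanMoietyMass(m) - tr$trueGlycanMass), 0.05)
    }
    empty <- simulateCohort(0, 0, params = clean)
    expect_equal(nrow(empty$truth), 0)
    expect_length(empty$spectra, 0)
})
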