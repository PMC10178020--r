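cleanParams <- simParams(ladderCompleteness = 1, byCoverage = 1,
                         nNoisePeaks = 0, seed = 17)

test_that("reference gating applies the 850 Da and 10% base-peak bounds", {
    s <- makeSpec(c(800, 900), c(100, 50))
    refs <- candidateReferences(s)
    expect_equal(refs$mz, 900)

    # both bounds are inclusive
    s2 <- makeSpec(c(850.0, 1000), c(10, 100))
    expect_equal(candidateReferences(s2)$mz, c(850, 1000))

    s3 <- makeSpec(c(300, 700, 849.9), c(5, 100, 90))
    expect_equal(nrow(candidateReferences(s3)), 0L)
    expect_equal(nrow(candidateReferences(makeSpec(numeric(0),
                                                   numeric(0)))), 0L)
})

test_that("pattern matching needs two peaks and a positive glycan mass", {
    sim <- simulateGlycopeptide("EEQYNSTYR", c(Hex = 5, HexNAc = 4),
                                2L, cleanParams)
    s <- sim$spectrum
    m <- matchPattern(s, sim$truth$trueY1Mz, 1000)
    expect_s4_class(m, "PatternMatch")
    expect_equal(nMatched(m), 8L)
    expect_equal(peptideMoietyMass(m), peptideNeutralMass("EEQYNSTYR"),
                 tolerance = 1e-6)

    # reference peak only: 1 < 2
    lone <- makeSpec(1000, 100, precursorMz = 1500, charge = 2L)
    expect_null(matchPattern(lone, 1000, 100))

    # one co-matching peak at the 0.05 Da tolerance boundary (offset
    # 203.0794 found 0.0406 Da off)
    two <- makeSpec(c(1000, 1203.12), c(100, 50), precursorMz = 1500,
                    charge = 2L)
    m2 <- matchPattern(two, 1000, 100)
    expect_equal(nMatched(m2), 2L)
    expect_equal(sort(m2@matchedOffsets), c(0, 203.0794))
    expect_null(matchPattern(two, 1000, 100, tolerance = 0.03))

    # glycan moiety mass must outweigh zero: precursor lighter than the
    # implied peptide moiety invalidates the match
    light <- makeSpec(c(1000, 1203.08), c(100, 50), precursorMz = 500,
                      charge = 1L)
    expect_null(matchPattern(light, 1000, 100))
})

test_that("shrinking the tolerance never gains pattern peaks", {
    set.seed(23)
    for (i in 1:8) {
        sim <- simulateGlycopeptide("VVLHPNYSQVDIGIK",
                                    c(Hex = 5, HexNAc = 4, NeuAc = 1), 2L,
                                    simParams(seed = 300 + i))
        s <- chargeDeconvolute(prefilterPeaks(sim$spectrum))
        tols <- c(0.05, 0.02, 0.01, 0.001)
        ns <- vapply(tols, function(tol) {
            m <- matchPattern(s, sim$truth$trueY1Mz, 1, tolerance = tol)
            if (is.null(m)) 1L else nMatched(m)
        }, integer(1))
        expect_true(all(diff(ns) <= 0))
    }
})

test_that("ranking sorts by matches, then intensity, then m/z", {
    # matchedOffsets must contain 0 (the reference) for validity
    mk <- function(n, int, mz = 1000) {
        offs <- c(0, patternTemplate()[patternTemplate() > 0])[seq_len(n)]
        new("PatternMatch", sourceId = "s", referenceMz = mz,
            referenceIntensity = int, matchedOffsets = offs,
            nMatched = as.integer(n), peptideMoietyMass = 700,
            glycanMoietyMass = 1500, rank = NA_integer_)
    }
    ranked <- rankPatterns(list(mk(5, 500), mk(5, 900), mk(3, 1e6)))
    expect_equal(vapply(ranked, function(m) m@referenceIntensity,
                        numeric(1)), c(900, 500, 1e6))
    expect_equal(vapply(ranked, matchRank, integer(1)), 1:3)

    tie <- rankPatterns(list(mk(4, 100, mz = 910), mk(4, 100, mz = 900)))
    expect_equal(vapply(tie, referenceMz, numeric(1)), c(900, 910))

    single <- rankPatterns(list(mk(2, 1)))
    expect_equal(matchRank(single[[1]]), 1L)
    expect_equal(rankPatterns(list()), list())
})

test_that("rank-1 recovers the peptide moiety exactly on clean spectra", {
    pools <- simulationPools()
    for (i in 1:20) {
        pep <- pools$glycoPeptides[(i - 1) %% 8 + 1]
        cmp <- pools$compositions[[(i - 1) %% 10 + 1]]
        sim <- simulateGlycopeptide(pep, cmp, 2L + i %% 2,
                                    simParams(ladderCompleteness = 1,
                                              byCoverage = 1,
                                              nNoisePeaks = 0,
                                              seed = 400 + i))
        s <- chargeDeconvolute(prefilterPeaks(sim$spectrum))
        top <- findPatterns(s)[[1]]
        expect_lt(abs(peptideMoietyMass(top) - peptideNeutralMass(pep)),
                  0.02)
        expect_equal(peptideMoietyMass(top) + glycanMoietyMass(top),
                     precursorNeutralMass(s), tolerance = 1e-9)
    }
})

test_that("isotope grouping links references k * 1.00335 apart", {
    mk <- function(mz) {
        new("PatternMatch", sourceId = "s", referenceMz = mz,
            referenceIntensity = 1, matchedOffsets = c(0, 203.0794),
            nMatched = 2L, peptideMoietyMass = 700,
            glycanMoietyMass = 1500, rank = NA_integer_)
    }
    g <- groupIsotopePatterns(list(mk(1000.00), mk(1001.00335)))
    expect_equal(g, c(1L, 1L))
    g2 <- groupIsotopePatterns(list(mk(1000.00), mk(1005.00)))
    expect_equal(g2, c(1L, 2L))
    expect_equal(groupIsotopePatterns(list(mk(1000))), 1L)
    # transitive: 0, +1, +2 isotopes form one group; a far reference not
    g3 <- groupIsotopePatterns(list(mk(1000), mk(1001.0034),
                                    mk(1002.0067), mk(1300)))
    expect_equal(g3, c(1L, 1L, 1L, 2L))
})
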