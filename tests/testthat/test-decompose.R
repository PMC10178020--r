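cleanAt <- function(seed) simParams(ladderCompleteness = 1, byCoverage = 1,
                                    nNoisePeaks = 0, seed = seed)

test_that("the peptide composite keeps b/y ions and drops glycan signal", {
    pep <- "GLTFQQNASSMCVPDQDTAIR"
    cmp <- c(Hex = 5, HexNAc = 4, dHex = 1, NeuAc = 1)
    sim <- simulateGlycopeptide(pep, cmp, 2L, cleanAt(51))
    res <- decomposeSpectrum(sim$spectrum)
    expect_equal(res$outcome, "decomposed")
    ps <- peptideSpectrum(res$pair)
    y1 <- sim$truth$trueY1Mz

    expect_equal(precursorMz(ps), y1, tolerance = 1e-6)
    expect_equal(precursorCharge(ps), 1L)
    # nothing above Y1 + 0.05 (the Y1 peak itself survives)
    expect_lte(max(peaks(ps)$mz), y1 + 0.05)
    expect_true(any(abs(peaks(ps)$mz - y1) < 1e-9))
    # no oxonium signal within 0.02 Da of the six-ion table
    for (mz in oxoniumTable()$mz)
        expect_false(any(abs(peaks(ps)$mz - mz) <= 0.02))
    # none of the Y2..Y5 ladder
    for (off in patternTemplate()[patternTemplate() > 0])
        expect_false(any(abs(peaks(ps)$mz - (y1 + off)) <= 0.02))
    # every simulated b/y and b/y + HexNAc ion at or below Y1 is retained
    aa <- strsplit(pep, "")[[1]]
    res_m <- vapply(aa, function(a) peptideNeutralMass(a) - waterMass(),
                    numeric(1))
    b <- cumsum(res_m)[1:(length(aa) - 1)] + protonMass()
    y <- rev(cumsum(rev(res_m)))[2:length(aa)] + waterMass() + protonMass()
    site <- 7  # first N-X-S/T sequon of GLTFQQNASSMCVPDQDTAIR
    i <- seq_len(length(aa) - 1)
    frag <- c(b, y,
              b[i >= site] + 203.07937,  # b+HexNAc spans the site
              y[i < site] + 203.07937)   # y_(n-i) spans it when i < site
    frag <- frag[frag <= y1 + 0.05]
    # fragments landing in an oxonium removal window are stripped by design
    inOxo <- vapply(frag, function(mz) {
        any(abs(mz - oxoniumTable()$mz) <= 0.02)
    }, logical(1))
    for (mz in frag[!inOxo])
        expect_true(any(abs(peaks(ps)$mz - mz) <= 0.001))
})

test_that("the glycan composite is untouched apart from metadata", {
    sim <- simulateGlycopeptide("EEQFNSTFR", c(Hex = 6, HexNAc = 2), 3L,
                                cleanAt(52))
    res <- decomposeSpectrum(sim$spectrum)
    gs <- glycanSpectrum(res$pair)
    parent <- chargeDeconvolute(prefilterPeaks(sim$spectrum))
    expect_equal(peaks(gs), peaks(parent))
    gm <- spectrumMetadata(gs)$glycanMoietyMass
    expect_lt(abs(gm - sim$truth$trueGlycanMass), 0.05)
    # exact mass conservation
    m <- patternMatch(res$pair)
    expect_equal(peptideMoietyMass(m) + gm,
                 precursorNeutralMass(sim$spectrum), tolerance = 1e-9)
})

test_that("a pattern from another spectrum is rejected", {
    simA <- simulateGlycopeptide("EEQYNSTYR", c(Hex = 5, HexNAc = 4), 2L,
                                 cleanAt(53))
    simB <- simulateGlycopeptide("EEQFNSTFR", c(Hex = 5, HexNAc = 4), 2L,
                                 cleanAt(54))
    patA <- findPatterns(chargeDeconvolute(prefilterPeaks(
        simA$spectrum)))[[1]]
    expect_error(makePeptideSpectrum(simB$spectrum, patA),
                 "derived from spectrum")
    expect_error(makeGlycanSpectrum(simB$spectrum, patA),
                 "derived from spectrum")
})

test_that("a spectrum with no glycan peaks above Y1 only changes precursor", {
    # hand-built: b/y-like peaks plus a reference, no oxonium, nothing
    # above the reference
    s <- makeSpec(c(300.1, 500.2, 700.3, 950.0), c(40, 60, 80, 100),
                  precursorMz = 1200, charge = 2L, id = "flat")
    m <- matchPattern(s, 950.0, 100,
                      template = c(-649.9, 0),  # synthetic 2-peak template
                      tolerance = 0.05)
    ps <- makePeptideSpectrum(s, m)
    expect_equal(peaks(ps)$mz, peaks(s)$mz)
    expect_equal(precursorMz(ps), 950.0)
    expect_equal(precursorCharge(ps), 1L)
})

test_that("the stream partitions spectra into the three outcomes", {
    cohort <- simulateCohort(10, 10, params = cleanAt(55))
    st <- decomposeStream(cohort$spectra)
    expect_equal(sum(st$counts), 20L)
    expect_equal(unname(st$counts["decomposed"]), 10L)
    expect_equal(unname(st$counts["non-glyco"]), 10L)
    # outcomes line up with the truth labels
    outcomes <- vapply(st$results, `[[`, character(1), "outcome")
    expect_equal(outcomes == "decomposed",
                 cohort$truth$label == "glyco")

    empty <- decomposeStream(list())
    expect_equal(sum(empty$counts), 0L)
    expect_length(empty$results, 0)
})

test_that("glyco spectra without a locatable pattern are flagged", {
    # oxonium ions present, but every peak below the 850 Da reference gate
    s <- makeSpec(c(204.0867, 366.1395, 500, 640), c(30, 40, 700, 230),
                  precursorMz = 900, charge = 2L, id = "nopattern")
    res <- decomposeSpectrum(s)
    expect_equal(res$outcome, "glyco-no-pattern")
    expect_true(isGlycopeptide(res$oxonium))
})

test_that("decomposition artifacts are written and read back", {
    cohort <- simulateCohort(4, 2, params = cleanAt(56))
    st <- decomposeStream(cohort$spectra)
    prefix <- file.path(withr::local_tempdir(), "run")
    files <- writeDecomposition(st, prefix, passthrough = TRUE)
    expect_true(all(file.exists(files)))
    pep <- readSpectra(files[["peptide"]])
    expect_length(pep, 4)
    expect_true(all(vapply(pep, precursorCharge, integer(1)) == 1L))
    tab <- read.delim(files[["glycan"]])
    expect_equal(nrow(tab), 4)
    expect_true(all(tab$glycan_moiety_mass > 0))
    expect_length(readSpectra(files[["passthrough"]]), 2)
})
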