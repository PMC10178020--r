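test_that("MGF blocks parse with sorted peaks and per-peak charge", {
    path <- withr::local_tempfile(fileext = ".mgf")
    writeLines(c(
        "BEGIN IONS",
        "TITLE=demo scan",
        "PEPMASS=1234.5678 9999.0",
        "CHARGE=2+",
        "400.2 55.0",
        "204.0867 10.0 1",
        "900.45 120.5 2",
        "END IONS"), path)
    sp <- readSpectra(path)
    expect_length(sp, 1)
    s <- sp[[1]]
    expect_equal(spectrumId(s), "demo scan")
    expect_equal(precursorMz(s), 1234.5678)
    expect_equal(precursorCharge(s), 2L)
    p <- peaks(s)
    expect_equal(p$mz, c(204.0867, 400.2, 900.45))
    expect_equal(p$charge, c(1L, NA_integer_, 2L))
})

test_that("empty files yield empty streams and malformed records fail loudly", {
    empty <- withr::local_tempfile(fileext = ".mgf")
    writeLines(character(0), empty)
    expect_length(readSpectra(empty), 0)

    bad <- withr::local_tempfile(fileext = ".mgf")
    writeLines(c("BEGIN IONS", "TITLE=t", "PEPMASS=500",
                 "not a peak line at all x", "END IONS"), bad)
    expect_error(readSpectra(bad), "line 4")
    writeLines(c("BEGIN IONS", "TITLE=t", "PEPMASS=500", "100 1"), bad)
    expect_error(readSpectra(bad), "unterminated")
    expect_error(readSpectra("/nonexistent.mgf"), "not found")
})

test_that("simulator output round-trips through MGF and ms2", {
    cohort <- simulateCohort(4, 3, params = simParams(seed = 5))
    mgf <- withr::local_tempfile(fileext = ".mgf")
    writeSpectra(cohort$spectra, mgf)
    back <- readSpectra(mgf)
    expect_length(back, 7)
    for (i in seq_along(back)) {
        expect_equal(spectrumId(back[[i]]), spectrumId(cohort$spectra[[i]]))
        expect_equal(precursorCharge(back[[i]]),
                     precursorCharge(cohort$spectra[[i]]))
        expect_equal(precursorMz(back[[i]]),
                     precursorMz(cohort$spectra[[i]]), tolerance = 1e-6)
        expect_equal(peaks(back[[i]])$mz, peaks(cohort$spectra[[i]])$mz,
                     tolerance = 1e-4)
        expect_equal(peaks(back[[i]])$intensity,
                     peaks(cohort$spectra[[i]])$intensity,
                     tolerance = 1e-2)
    }
    ms2 <- withr::local_tempfile(fileext = ".ms2")
    writeSpectra(cohort$spectra, ms2)
    back2 <- readSpectra(ms2)
    expect_length(back2, 7)
    expect_equal(vapply(back2, precursorMz, numeric(1)),
                 vapply(cohort$spectra, precursorMz, numeric(1)),
                 tolerance = 1e-6)
    expect_equal(vapply(back2, precursorCharge, integer(1)),
                 vapply(cohort$spectra, precursorCharge, integer(1)))
    expect_equal(vapply(back2, peakCount, integer(1)),
                 vapply(cohort$spectra, peakCount, integer(1)))
})

test_that("the intensity prefilter is inclusive, monotone and idempotent", {
    s <- makeSpec(c(100, 200, 300), c(10, 15, 20))
    f <- prefilterPeaks(s, 15)
    expect_equal(peaks(f)$intensity, c(15, 20))
    expect_equal(peaks(prefilterPeaks(s, 0))$mz, peaks(s)$mz)
    expect_equal(peakCount(prefilterPeaks(s, 100)), 0L)
    expect_s4_class(prefilterPeaks(s, 100), "Spectrum")
    set.seed(9)
    for (i in 1:10) {
        r <- makeSpec(sort(runif(40, 100, 2000)), runif(40, 0, 60))
        thr <- runif(1, 0, 50)
        f1 <- prefilterPeaks(r, thr)
        expect_lte(sum(peaks(f1)$intensity), sum(peaks(r)$intensity))
        expect_equal(peaks(prefilterPeaks(f1, thr)), peaks(f1))
    }
})

test_that("precursor neutral mass inverts the m/z convention", {
    M <- 1567.789
    s <- makeSpec(500, 10, precursorMz = M + 1.00727646, charge = 1L)
    expect_equal(precursorNeutralMass(s), M, tolerance = 1e-9)
    s2 <- makeSpec(500, 10, precursorMz = 1000, charge = 2L)
    expect_equal(precursorNeutralMass(s2), 1997.9854471, tolerance = 1e-6)
    s3 <- makeSpec(500, 10, precursorMz = 1000, charge = NA_integer_)
    expect_error(precursorNeutralMass(s3), "charge unknown")
})

test_that("charge deconvolution converts to 1+ and merges duplicates", {
    s <- makeSpec(c(300, 500), c(5, 10), peakCharge = c(1L, 1L))
    expect_equal(peaks(chargeDeconvolute(s)), peaks(s))

    s2 <- makeSpec(500, 10, peakCharge = 2L)
    expect_equal(peaks(chargeDeconvolute(s2))$mz, 998.99272,
                 tolerance = 1e-5)
    expect_equal(peaks(chargeDeconvolute(s2))$charge, 1L)

    # a 2+ peak deconvolving onto an existing 1+ peak within 0.001 Da
    s3 <- makeSpec(c(500.0, 998.9929), c(10, 7),
                   peakCharge = c(2L, 1L))
    d3 <- chargeDeconvolute(s3)
    expect_equal(peakCount(d3), 1L)
    expect_equal(peaks(d3)$intensity, 17)

    # idempotence on simulated and random spectra
    set.seed(21)
    for (i in 1:10) {
        z <- sample(c(NA_integer_, 1L, 2L, 3L), 30, replace = TRUE)
        r <- makeSpec(sort(runif(30, 200, 1500)), runif(30, 1, 100),
                      peakCharge = z)
        d1 <- chargeDeconvolute(r)
        expect_equal(peaks(chargeDeconvolute(d1)), peaks(d1),
                     tolerance = 1e-12)
        expect_equal(sum(peaks(d1)$intensity), sum(peaks(r)$intensity))
    }
})
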