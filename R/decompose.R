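#' DecomposedPair: the two composite spectra from one hybrid spectrum
#'
#' Result of decomposing one glycopeptide fragmentation spectrum: a
#' peptide-moiety composite spectrum whose pseudo-precursor is the
#' reference (Y1) peak at charge 1, and a glycan-moiety spectrum carrying
#' the inferred glycan mass in its metadata.
#'
#' @slot peptideSpectrum [Spectrum-class] with precursor
#'   `(referenceMz, 1+)`, oxonium peaks removed and all peaks above the
#'   reference truncated.
#' @slot glycanSpectrum Charge-deconvoluted copy of the parent with
#'   metadata key `glycanMoietyMass`.
#' @slot sourceId Identifier of the parent spectrum.
#' @slot pattern The [PatternMatch-class] used (rank 1).
#'
#' @aliases DecomposedPair-class
#' @exportClass DecomposedPair
setClass("DecomposedPair",
    representation(
        peptideSpectrum = "Spectrum",
        glycanSpectrum = "Spectrum",
        sourceId = "character",
        pattern = "PatternMatch"
    )
)

setValidity("DecomposedPair", function(object) {
    msg <- character(0)
    ps <- object@peptideSpectrum
    if (precursorCharge(ps) != 1L)
        msg <- c(msg, "peptide spectrum precursor charge must be 1")
    if (abs(precursorMz(ps) - object@pattern@referenceMz) > 1e-9)
        msg <- c(msg,
                 "peptide spectrum precursor must equal the reference m/z")
    if (is.null(spectrumMetadata(object@glycanSpectrum)$glycanMoietyMass))
        msg <- c(msg, "glycan spectrum must carry glycanMoietyMass")
    if (length(msg)) msg else TRUE
})

setMethod("show", "DecomposedPair", function(object) {
    cat("DecomposedPair (spectrum '", object@sourceId, "')\n",
        "  peptide moiety: pseudo-precursor ",
        format(precursorMz(object@peptideSpectrum), digits = 9),
        " (1+), ", peakCount(object@peptideSpectrum), " peaks\n",
        "  glycan moiety mass: ",
        format(object@pattern@glycanMoietyMass, digits = 9), " Da\n",
        sep = "")
})

#' @describeIn decomposeSpectrum Accessors for `DecomposedPair`.
#' @export
setGeneric("peptideSpectrum", function(x) standardGeneric("peptideSpectrum"))

#' @rdname decomposeSpectrum
#' @export
setMethod("peptideSpectrum", "DecomposedPair",
          function(x) x@peptideSpectrum)

#' @rdname decomposeSpectrum
#' @export
setGeneric("glycanSpectrum", function(x) standardGeneric("glycanSpectrum"))

#' @rdname decomposeSpectrum
#' @export
setMethod("glycanSpectrum", "DecomposedPair", function(x) x@glycanSpectrum)

#' @rdname decomposeSpectrum
#' @export
setGeneric("patternMatch", function(x) standardGeneric("patternMatch"))

#' @rdname decomposeSpectrum
#' @export
setMethod("patternMatch", "DecomposedPair", function(x) x@pattern)

#' @rdname decomposeSpectrum
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname decomposeSpectrum
#' @export
setMethod("sourceId", "DecomposedPair", function(x) x@sourceId)

.checkPatternSource <- function(spectrum, pattern) {
    if (spectrumId(spectrum) != pattern@sourceId)
        stop("pattern was derived from spectrum '", pattern@sourceId,
             "', not from '", spectrumId(spectrum), "'")
}

#' Build the peptide-moiety composite spectrum
#'
#' In order: (1) charge-deconvolute; (2) delete every peak within
#' `oxoniumTolerance` of any oxonium table m/z; (3) delete every peak with
#' m/z greater than `referenceMz + patternTolerance` (so the Y1 peak
#' itself survives); (4) set the precursor to `(referenceMz, 1+)`.
#'
#' @param spectrum The parent (prefiltered) [Spectrum-class].
#' @param pattern The selected [PatternMatch-class] for this spectrum.
#' @param config Configuration list (see [defaultConfig()]).
#' @return The peptide-moiety [Spectrum-class].
#' @export
makePeptideSpectrum <- function(spectrum, pattern,
                                config = defaultConfig()) {
    stopifnot(is(spectrum, "Spectrum"), is(pattern, "PatternMatch"))
    .checkPatternSource(spectrum, pattern)
    s <- chargeDeconvolute(spectrum, config$mergeTolerance)
    p <- peaks(s)
    oxo <- config$oxoniumIons$mz
    isOxo <- vapply(p$mz, function(m) {
        any(abs(m - oxo) <= config$oxoniumTolerance)
    }, logical(1L))
    keep <- !isOxo & p$mz <= pattern@referenceMz + config$patternTolerance
    s <- .withPeaks(s, p[keep, , drop = FALSE])
    s@precursorMz <- pattern@referenceMz
    s@precursorCharge <- 1L
    validObject(s)
    s
}

#' Build the glycan-moiety spectrum
#'
#' A charge-deconvoluted copy of the parent with the inferred glycan
#' moiety mass recorded under the metadata key `glycanMoietyMass`; the
#' peak list is otherwise untouched.
#'
#' @inheritParams makePeptideSpectrum
#' @return The glycan-moiety [Spectrum-class].
#' @export
makeGlycanSpectrum <- function(spectrum, pattern,
                               config = defaultConfig()) {
    stopifnot(is(spectrum, "Spectrum"), is(pattern, "PatternMatch"))
    .checkPatternSource(spectrum, pattern)
    s <- chargeDeconvolute(spectrum, config$mergeTolerance)
    md <- spectrumMetadata(s)
    md$glycanMoietyMass <- pattern@glycanMoietyMass
    spectrumMetadata(s) <- md
    s
}

#' Decompose one spectrum
#'
#' Runs the full three-step pipeline on a single spectrum: intensity
#' prefilter, oxonium-ion classification, core-pattern search, and
#' decomposition. The outcome is one of:
#' \describe{
#'   \item{`"non-glyco"`}{failed the oxonium filter; the spectrum is
#'     passed through unmodified (`spectrum` element).}
#'   \item{`"decomposed"`}{a rank-1 pattern was found; `pair` holds the
#'     [DecomposedPair-class] and `patterns` all ranked matches.}
#'   \item{`"glyco-no-pattern"`}{classified as glycopeptide but no usable
#'     pattern placement was found.}
#' }
#'
#' @param spectrum A [Spectrum-class].
#' @param config Configuration list (see [defaultConfig()]).
#' @param x A `DecomposedPair`.
#' @return A list with elements `outcome`, `id`, `oxonium` (the
#'   [OxoniumResult-class]) and, depending on the outcome, `spectrum`,
#'   `pair`, `patterns`.
#' @export
decomposeSpectrum <- function(spectrum, config = defaultConfig()) {
    stopifnot(is(spectrum, "Spectrum"))
    filtered <- prefilterPeaks(spectrum, config$minPeakIntensity)
    oxo <- detectOxonium(filtered, config$oxoniumIons,
                         config$oxoniumTolerance, config$minOxoniumIons,
                         config$oxoniumSumThreshold)
    if (!isGlycopeptide(oxo))
        return(list(outcome = "non-glyco", id = spectrumId(spectrum),
                    oxonium = oxo, spectrum = spectrum))
    deconv <- chargeDeconvolute(filtered, config$mergeTolerance)
    patterns <- findPatterns(deconv, config)
    if (!length(patterns))
        return(list(outcome = "glyco-no-pattern",
                    id = spectrumId(spectrum), oxonium = oxo,
                    spectrum = spectrum))
    top <- patterns[[1L]]
    pair <- new("DecomposedPair",
                peptideSpectrum = makePeptideSpectrum(filtered, top,
                                                      config),
                glycanSpectrum = makeGlycanSpectrum(filtered, top, config),
                sourceId = spectrumId(spectrum), pattern = top)
    list(outcome = "decomposed", id = spectrumId(spectrum), oxonium = oxo,
         pair = pair, patterns = patterns)
}

#' Decompose a stream of spectra
#'
#' Applies [decomposeSpectrum()] to each spectrum. Per-spectrum failures
#' are caught, logged and skipped ("error" outcome); they never abort the
#' stream. Outcome counts always sum to the number of input spectra.
#'
#' @param spectra List of [Spectrum-class] objects (or a path readable by
#'   [readSpectra()]).
#' @param config Configuration list.
#' @param verbose Emit a per-stage summary message.
#' @return A list with `results` (one entry per spectrum, as in
#'   [decomposeSpectrum()]) and `counts` (named integer vector over
#'   outcomes `non-glyco`, `decomposed`, `glyco-no-pattern`, `error`).
#' @examples
#' cohort <- simulateCohort(3, 3, params = simParams(seed = 7))
#' res <- decomposeStream(cohort$spectra)
#' res$counts
#' @export
decomposeStream <- function(spectra, config = defaultConfig(),
                            verbose = FALSE) {
    if (is.character(spectra))
        spectra <- readSpectra(spectra)
    results <- vector("list", length(spectra))
    for (i in seq_along(spectra)) {
        results[[i]] <- tryCatch(
            decomposeSpectrum(spectra[[i]], config),
            error = function(e) {
                warning("spectrum ", i, " ('",
                        tryCatch(spectrumId(spectra[[i]]),
                                 error = function(...) "?"),
                        "') skipped: ", conditionMessage(e),
                        call. = FALSE)
                list(outcome = "error", id = NA_character_)
            })
    }
    outcomes <- vapply(results, `[[`, character(1L), "outcome")
    counts <- vapply(c("non-glyco", "decomposed", "glyco-no-pattern",
                       "error"),
                     function(o) sum(outcomes == o), integer(1L))
    if (verbose)
        message(length(spectra), " spectra: ",
                paste(names(counts), counts, sep = "=", collapse = ", "))
    list(results = results, counts = counts)
}

#' Write decomposition results to disk
#'
#' Writes the peptide-moiety composite spectra as an ms2 file
#' (`<prefix>_peptide.ms2`), the glycan-moiety records as a tab-separated
#' table (`<prefix>_glycan.tsv`: source id, reference m/z, peptide and
#' glycan moiety masses, matched peaks, number of ranked patterns) and,
#' optionally, the non-glycopeptide passthrough spectra as an MGF
#' (`<prefix>_passthrough.mgf`).
#'
#' @param stream Result of [decomposeStream()].
#' @param prefix Output path prefix.
#' @param passthrough Also write the non-glyco spectra as MGF.
#' @return Named character vector of the files written, invisibly.
#' @export
writeDecomposition <- function(stream, prefix, passthrough = FALSE) {
    results <- stream$results
    pairs <- Filter(function(r) r$outcome == "decomposed", results)
    pepPath <- paste0(prefix, "_peptide.ms2")
    glyPath <- paste0(prefix, "_glycan.tsv")
    writeSpectra(lapply(pairs, function(r) peptideSpectrum(r$pair)),
                 pepPath, format = "ms2")
    tab <- do.call(rbind, lapply(pairs, function(r) {
        m <- patternMatch(r$pair)
        data.frame(source_id = sourceId(r$pair),
                   reference_mz = m@referenceMz,
                   peptide_moiety_mass = m@peptideMoietyMass,
                   glycan_moiety_mass = m@glycanMoietyMass,
                   n_matched = m@nMatched,
                   n_patterns = length(r$patterns),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(tab))
        tab <- data.frame(source_id = character(0),
                          reference_mz = numeric(0),
                          peptide_moiety_mass = numeric(0),
                          glycan_moiety_mass = numeric(0),
                          n_matched = integer(0), n_patterns = integer(0))
    utils::write.table(tab, glyPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(peptide = pepPath, glycan = glyPath)
    if (passthrough) {
        ptPath <- paste0(prefix, "_passthrough.mgf")
        pt <- Filter(function(r) r$outcome == "non-glyco", results)
        writeSpectra(lapply(pt, `[[`, "spectrum"), ptPath, format = "mgf")
        files <- c(files, passthrough = ptPath)
    }
    invisible(files)
}
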