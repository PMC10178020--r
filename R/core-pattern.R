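#' PatternMatch: one placement of the N-glycan core Y-ion pattern
#'
#' A candidate placement of the eight-peak core fragmentation pattern
#' anchored at a reference peak (the putative Y1 = peptide + HexNAc,
#' singly protonated), with the peptide- and glycan-moiety masses it
#' implies:
#' `peptideMoietyMass = (referenceMz - proton) - HexNAc` and
#' `glycanMoietyMass = precursor neutral mass - peptideMoietyMass`.
#'
#' @slot sourceId Identifier of the spectrum the match was found in.
#' @slot referenceMz m/z of the reference (candidate Y1) peak.
#' @slot referenceIntensity Intensity of the reference peak.
#' @slot matchedOffsets Offsets of the template that found a peak (always
#'   includes 0, the reference itself).
#' @slot nMatched Number of matched offsets (>= 2 for a usable match).
#' @slot peptideMoietyMass Neutral peptide moiety mass in Da.
#' @slot glycanMoietyMass Neutral glycan moiety mass in Da (> 0).
#' @slot rank Rank among the matches of one spectrum (1 = selected), or
#'   `NA` before ranking.
#'
#' @aliases PatternMatch-class
#' @exportClass PatternMatch
setClass("PatternMatch",
    representation(
        sourceId = "character",
        referenceMz = "numeric",
        referenceIntensity = "numeric",
        matchedOffsets = "numeric",
        nMatched = "integer",
        peptideMoietyMass = "numeric",
        glycanMoietyMass = "numeric",
        rank = "integer"
    )
)

setValidity("PatternMatch", function(object) {
    msg <- character(0)
    if (object@nMatched != length(object@matchedOffsets))
        msg <- c(msg, "nMatched must equal length(matchedOffsets)")
    if (object@nMatched < 2L)
        msg <- c(msg, "a pattern match needs at least 2 matched peaks")
    if (!any(object@matchedOffsets == 0))
        msg <- c(msg, "matchedOffsets must contain the reference (0)")
    if (!is.na(object@glycanMoietyMass) && object@glycanMoietyMass <= 0)
        msg <- c(msg, "glycanMoietyMass must be positive")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PatternMatch", function(object) {
    cat("PatternMatch (spectrum '", object@sourceId, "')\n",
        "  reference m/z ", format(object@referenceMz, digits = 9),
        ", intensity ", format(object@referenceIntensity, digits = 4),
        if (!is.na(object@rank)) paste0(", rank ", object@rank) else "",
        "\n  ", object@nMatched, "/8 pattern peaks matched\n",
        "  peptide moiety ", format(object@peptideMoietyMass, digits = 9),
        " Da, glycan moiety ",
        format(object@glycanMoietyMass, digits = 9), " Da\n", sep = "")
})

#' @describeIn findPatterns Accessors for `PatternMatch`.
#' @export
setGeneric("referenceMz", function(x) standardGeneric("referenceMz"))

#' @rdname findPatterns
#' @export
setMethod("referenceMz", "PatternMatch", function(x) x@referenceMz)

#' @rdname findPatterns
#' @export
setGeneric("peptideMoietyMass",
           function(x) standardGeneric("peptideMoietyMass"))

#' @rdname findPatterns
#' @export
setMethod("peptideMoietyMass", "PatternMatch",
          function(x) x@peptideMoietyMass)

#' @rdname findPatterns
#' @export
setGeneric("glycanMoietyMass", function(x) standardGeneric("glycanMoietyMass"))

#' @rdname findPatterns
#' @export
setMethod("glycanMoietyMass", "PatternMatch", function(x) x@glycanMoietyMass)

#' @rdname findPatterns
#' @export
setGeneric("nMatched", function(x) standardGeneric("nMatched"))

#' @rdname findPatterns
#' @export
setMethod("nMatched", "PatternMatch", function(x) x@nMatched)

#' @rdname findPatterns
#' @export
setGeneric("matchRank", function(x) standardGeneric("matchRank"))

#' @rdname findPatterns
#' @export
setMethod("matchRank", "PatternMatch", function(x) x@rank)

#' Candidate reference (Y1) peaks
#'
#' Returns the peaks eligible to anchor a pattern match: m/z at least
#' `minMz` and intensity at least `minRelIntensity` times the base peak
#' intensity (both bounds inclusive), in ascending m/z. The reference gate
#' keeps the pattern search away from small fragments below any plausible
#' peptide moiety mass and from noise-level peaks.
#'
#' @param spectrum A charge-deconvoluted, prefiltered [Spectrum-class].
#' @param minMz Minimum reference m/z in Da (default 850).
#' @param minRelIntensity Minimum intensity as a fraction of the base peak
#'   (default 0.1).
#' @return data.frame with columns `mz` and `intensity` (possibly empty).
#' @export
candidateReferences <- function(spectrum, minMz = 850,
                                minRelIntensity = 0.1) {
    stopifnot(is(spectrum, "Spectrum"))
    p <- peaks(spectrum)
    if (nrow(p) == 0L)
        return(data.frame(mz = numeric(0), intensity = numeric(0)))
    keep <- p$mz >= minMz & p$intensity >= minRelIntensity * max(p$intensity)
    out <- p[keep, c("mz", "intensity"), drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Match the core pattern at one reference peak
#'
#' For each template offset `o`, a peak within `tolerance` of
#' `referenceMz + o` counts as a match (the most intense in-window peak;
#' offset 0 always matches the reference itself). A [PatternMatch-class]
#' is returned only when at least `minPeaks` offsets matched and the
#' implied glycan moiety mass is positive; otherwise `NULL`. Offsets whose
#' target m/z is non-positive or below the spectrum's first peak are
#' simply unmatched.
#'
#' @param spectrum A charge-deconvoluted, prefiltered [Spectrum-class]
#'   with known precursor charge.
#' @param referenceMz,referenceIntensity The candidate reference peak
#'   (from [candidateReferences()]).
#' @param template Offset template; default [patternTemplate()].
#' @param tolerance m/z matching tolerance in Da (default 0.05).
#' @param minPeaks Minimum number of matched offsets (default 2).
#' @param hexNAcMass HexNAc residue mass used to derive the peptide moiety
#'   mass from the reference.
#' @return A [PatternMatch-class] or `NULL`.
#' @export
matchPattern <- function(spectrum, referenceMz, referenceIntensity,
                         template = patternTemplate(), tolerance = 0.05,
                         minPeaks = 2L,
                         hexNAcMass = monosaccharideTable()$mass[
                             monosaccharideTable()$name == "HexNAc"]) {
    stopifnot(is(spectrum, "Spectrum"), tolerance > 0)
    p <- peaks(spectrum)
    matched <- vapply(template, function(o) {
        if (o == 0) return(TRUE)
        target <- referenceMz + o
        if (target <= 0) return(FALSE)
        any(abs(p$mz - target) <= tolerance)
    }, logical(1L))
    if (sum(matched) < minPeaks)
        return(NULL)
    pepMass <- (referenceMz - .protonMass) - hexNAcMass
    glyMass <- precursorNeutralMass(spectrum) - pepMass
    if (glyMass <= 0)
        return(NULL)
    new("PatternMatch", sourceId = spectrumId(spectrum),
        referenceMz = referenceMz,
        referenceIntensity = referenceIntensity,
        matchedOffsets = template[matched],
        nMatched = as.integer(sum(matched)),
        peptideMoietyMass = pepMass, glycanMoietyMass = glyMass,
        rank = NA_integer_)
}

#' Rank pattern matches of one spectrum
#'
#' Sorts descending by number of matched pattern peaks, ties broken
#' descending by reference peak intensity, remaining ties ascending by
#' reference m/z, and assigns ranks 1..k. The rank-1 match is the
#' decomposition choice.
#'
#' @param matches List of [PatternMatch-class] objects from one spectrum.
#' @return The sorted list with `rank` slots assigned.
#' @export
rankPatterns <- function(matches) {
    if (!length(matches))
        return(list())
    n <- vapply(matches, nMatched, integer(1L))
    int <- vapply(matches, function(m) m@referenceIntensity, numeric(1L))
    mz <- vapply(matches, referenceMz, numeric(1L))
    o <- order(-n, -int, mz)
    matches <- matches[o]
    for (i in seq_along(matches))
        matches[[i]]@rank <- i
    matches
}

#' Find and rank all core-pattern placements in a spectrum
#'
#' Convenience wrapper: gates candidate reference peaks, matches the
#' template at each, and ranks the resulting matches.
#'
#' @param spectrum A charge-deconvoluted, prefiltered [Spectrum-class].
#' @param config Configuration list (see [defaultConfig()]).
#' @param x A `PatternMatch`.
#' @return List of ranked [PatternMatch-class] objects (possibly empty).
#' @examples
#' sim <- simulateGlycopeptide("EEQYNSTYR", c(Hex = 5, HexNAc = 4),
#'                             charge = 2L, params = simParams(
#'                                 ladderCompleteness = 1, byCoverage = 1,
#'                                 nNoisePeaks = 0, seed = 1))
#' top <- findPatterns(sim$spectrum)[[1]]
#' top
#' @export
findPatterns <- function(spectrum, config = defaultConfig()) {
    refs <- candidateReferences(spectrum, config$minReferenceMz,
                                config$minReferenceRelIntensity)
    hexnac <- config$monosaccharides$mass[
        config$monosaccharides$name == "HexNAc"]
    matches <- vector("list", nrow(refs))
    for (i in seq_len(nrow(refs))) {
        matches[[i]] <- matchPattern(spectrum, refs$mz[i],
                                     refs$intensity[i],
                                     config$patternOffsets,
                                     config$patternTolerance,
                                     config$minPatternPeaks, hexnac)
    }
    rankPatterns(Filter(Negate(is.null), matches))
}

#' Group pattern matches that point to different isotopes of one species
#'
#' Matches whose reference m/z values differ by k times the 13C-12C
#' spacing (1 <= k <= `maxK`) within `tolerance` are placed in one group
#' (transitively). Used for reporting and evaluation, not for ranking.
#'
#' @param matches List of [PatternMatch-class] objects.
#' @param spacing Isotope spacing in Da (default 1.00335).
#' @param maxK Maximum isotope offset (default 3).
#' @param tolerance Matching tolerance in Da (default 0.05).
#' @return Integer vector of group ids, one per match.
#' @export
groupIsotopePatterns <- function(matches, spacing = 1.00335, maxK = 3L,
                                 tolerance = 0.05) {
    n <- length(matches)
    if (n == 0L)
        return(integer(0))
    mz <- vapply(matches, referenceMz, numeric(1L))
    ## adjacency under the isotope-offset relation, then connected
    ## components by label propagation
    group <- seq_len(n)
    repeat {
        changed <- FALSE
        for (i in seq_len(n)) {
            for (j in seq_len(n)) {
                if (group[i] == group[j]) next
                d <- abs(mz[i] - mz[j])
                if (any(abs(d - seq_len(maxK) * spacing) <= tolerance)) {
                    g <- min(group[i], group[j])
                    group[group == group[i] | group == group[j]] <- g
                    changed <- TRUE
                }
            }
        }
        if (!changed) break
    }
    match(group, unique(group))
}
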