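#' OxoniumResult: per-spectrum oxonium ion detections
#'
#' Holds the oxonium ion matches found in one spectrum, the summed
#' relative intensity driving the glycopeptide / non-glycopeptide
#' decision, and the decision itself.
#'
#' @slot matches data.frame with columns `name` (oxonium ion), `mz`
#'   (matched peak m/z) and `intensity` (matched peak intensity); at most
#'   one row per table entry, at most one entry per peak.
#' @slot relativeIntensitySum Sum of matched intensities divided by the
#'   total intensity of the spectrum; in [0, 1].
#' @slot nIonsDetected Number of distinct oxonium table entries matched.
#' @slot isGlycopeptide Classification under the thresholds in force.
#'
#' @aliases OxoniumResult-class
#' @exportClass OxoniumResult
setClass("OxoniumResult",
    representation(
        matches = "data.frame",
        relativeIntensitySum = "numeric",
        nIonsDetected = "integer",
        isGlycopeptide = "logical"
    )
)

setValidity("OxoniumResult", function(object) {
    msg <- character(0)
    s <- object@relativeIntensitySum
    if (length(s) != 1L || is.na(s) || s < 0 || s > 1)
        msg <- c(msg, "relativeIntensitySum must lie in [0, 1]")
    if (object@nIonsDetected != nrow(object@matches))
        msg <- c(msg, "nIonsDetected must equal the number of matches")
    if (length(msg)) msg else TRUE
})

setMethod("show", "OxoniumResult", function(object) {
    cat("OxoniumResult: ", object@nIonsDetected, " ion(s) detected, ",
        "relative intensity sum ",
        format(object@relativeIntensitySum, digits = 4),
        ", glycopeptide: ", object@isGlycopeptide, "\n", sep = "")
    if (nrow(object@matches)) {
        print(object@matches, row.names = FALSE)
    }
})

#' @describeIn detectOxonium Matched ion table accessor.
#' @export
setGeneric("oxoniumMatches", function(x) standardGeneric("oxoniumMatches"))

#' @rdname detectOxonium
#' @export
setMethod("oxoniumMatches", "OxoniumResult", function(x) x@matches)

#' @rdname detectOxonium
#' @export
setGeneric("relativeIntensitySum",
           function(x) standardGeneric("relativeIntensitySum"))

#' @rdname detectOxonium
#' @export
setMethod("relativeIntensitySum", "OxoniumResult",
          function(x) x@relativeIntensitySum)

#' @rdname detectOxonium
#' @export
setGeneric("isGlycopeptide", function(x) standardGeneric("isGlycopeptide"))

#' @rdname detectOxonium
#' @export
setMethod("isGlycopeptide", "OxoniumResult", function(x) x@isGlycopeptide)

#' Detect diagnostic oxonium ions and classify a spectrum
#'
#' For each oxonium table entry the single most intense peak within the
#' m/z tolerance is taken as its match; a peak may serve as the match for
#' at most one entry (on conflict the entry closest in m/z wins and the
#' other entry falls back to its next most intense in-window peak). The
#' relative intensity sum is the summed intensity of matched peaks divided
#' by the total intensity of the (prefiltered) spectrum, which makes it
#' invariant under uniform intensity scaling. A spectrum is classified as
#' a glycopeptide spectrum when at least `minIons` distinct ions are
#' detected and the relative intensity sum reaches `sumThreshold` (both
#' bounds inclusive).
#'
#' @param spectrum A prefiltered [Spectrum-class].
#' @param oxoniumIons Oxonium m/z table; default [oxoniumTable()].
#' @param tolerance m/z matching tolerance in Da (default 0.02).
#' @param minIons Minimum number of distinct oxonium ions (default 1).
#' @param sumThreshold Minimum relative intensity sum (default 0.0047).
#' @param x An `OxoniumResult`.
#' @return [detectOxonium()]: an [OxoniumResult-class].
#' @examples
#' s <- Spectrum("s1", 1200, 2L,
#'               mz = c(204.0868, 366.1395, 900, 1100),
#'               intensity = c(40, 60, 500, 400))
#' detectOxonium(s)
#' @export
detectOxonium <- function(spectrum, oxoniumIons = oxoniumTable(),
                          tolerance = 0.02, minIons = 1L,
                          sumThreshold = 0.0047) {
    stopifnot(is(spectrum, "Spectrum"), tolerance > 0)
    p <- peaks(spectrum)
    total <- sum(p$intensity)
    empty <- data.frame(name = character(0), mz = numeric(0),
                        intensity = numeric(0), stringsAsFactors = FALSE)
    if (nrow(p) == 0L || total <= 0) {
        res <- new("OxoniumResult", matches = empty,
                   relativeIntensitySum = 0, nIonsDetected = 0L,
                   isGlycopeptide = FALSE)
        return(classifyGlyco(res, minIons, sumThreshold, update = TRUE))
    }
    ## candidate (entry, peak) pairs within tolerance
    cand <- do.call(rbind, lapply(seq_len(nrow(oxoniumIons)), function(i) {
        hit <- which(abs(p$mz - oxoniumIons$mz[i]) <= tolerance)
        if (!length(hit)) return(NULL)
        data.frame(entry = i, peak = hit,
                   delta = abs(p$mz[hit] - oxoniumIons$mz[i]),
                   intensity = p$intensity[hit])
    }))
    matches <- empty
    if (!is.null(cand) && nrow(cand)) {
        takenPeak <- integer(0)
        assigned <- stats::setNames(rep(NA_integer_,
                                        nrow(oxoniumIons)),
                                    NULL)
        ## iterate: each unassigned entry claims its most intense free
        ## in-window peak; contested peaks go to the closest entry in m/z
        repeat {
            open <- which(is.na(assigned))
            open <- open[open %in% cand$entry]
            claims <- NULL
            for (e in open) {
                rows <- cand[cand$entry == e & !(cand$peak %in% takenPeak), ,
                             drop = FALSE]
                if (!nrow(rows)) next
                best <- rows[order(-rows$intensity, rows$delta), ][1L, ]
                claims <- rbind(claims, best)
            }
            if (is.null(claims) || !nrow(claims)) break
            for (pk in unique(claims$peak)) {
                contested <- claims[claims$peak == pk, , drop = FALSE]
                winner <- contested[order(contested$delta), ][1L, ]
                assigned[winner$entry] <- winner$peak
                takenPeak <- c(takenPeak, winner$peak)
            }
        }
        hit <- which(!is.na(assigned))
        if (length(hit)) {
            matches <- data.frame(
                name = oxoniumIons$name[hit],
                mz = p$mz[assigned[hit]],
                intensity = p$intensity[assigned[hit]],
                stringsAsFactors = FALSE)
        }
    }
    res <- new("OxoniumResult", matches = matches,
               relativeIntensitySum = sum(matches$intensity) / total,
               nIonsDetected = nrow(matches), isGlycopeptide = FALSE)
    classifyGlyco(res, minIons, sumThreshold, update = TRUE)
}

#' Glycopeptide classification from an oxonium detection result
#'
#' @param result An [OxoniumResult-class].
#' @param update If `TRUE`, return the `OxoniumResult` with its
#'   `isGlycopeptide` slot set; if `FALSE` (default) return the logical
#'   decision.
#' @return Logical, or an updated `OxoniumResult` when `update = TRUE`.
#' @rdname detectOxonium
#' @export
classifyGlyco <- function(result, minIons = 1L, sumThreshold = 0.0047,
                          update = FALSE) {
    stopifnot(is(result, "OxoniumResult"))
    decision <- result@nIonsDetected >= minIons &&
        result@relativeIntensitySum >= sumThreshold
    if (!update)
        return(decision)
    result@isGlycopeptide <- decision
    result
}
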