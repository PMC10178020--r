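#' Enumerate glycan compositions matching a mass
#'
#' Exhaustively enumerates every monosaccharide count vector within the
#' per-residue bounds of `table` whose mass lies within `tolerance` of the
#' query mass -- no more, no fewer. The search is a depth-first walk over
#' the count bounds with residual-mass pruning, which is set-equivalent to
#' a full nested-loop enumeration; completeness is the contract. This is
#' deliberately database-independent: unexpected (e.g. disease-specific)
#' compositions are reported as long as they fit the mass.
#'
#' @param queryMass Neutral glycan moiety mass in Da (> 0).
#' @param table Monosaccharide residue mass table with bounds; default
#'   [monosaccharideTable()] (Hex 0--12, HexNAc 1--7, dHex 0--3,
#'   NeuAc 0--4).
#' @param tolerance Mass tolerance in Da (default 0.1).
#' @return data.frame with one column per monosaccharide (in table
#'   order), plus `mass` and `delta` (composition mass minus query mass,
#'   signed). Sorted by `abs(delta)` ascending, ties broken
#'   lexicographically by counts.
#' @examples
#' generateCompositions(glycanMass(c(Hex = 5, HexNAc = 4, NeuAc = 2)))
#' @export
generateCompositions <- function(queryMass, table = monosaccharideTable(),
                                 tolerance = 0.1) {
    if (!is.numeric(queryMass) || length(queryMass) != 1L ||
        is.na(queryMass) || queryMass <= 0)
        stop("queryMass must be a single positive number")
    stopifnot(tolerance > 0)
    .checkMonosaccharideTable(table)
    n <- nrow(table)
    lo <- queryMass - tolerance
    hi <- queryMass + tolerance
    ## heaviest residue first so pruning bites early
    ord <- order(-table$mass)
    mass <- table$mass[ord]
    mn <- table$min[ord]
    mx <- table$max[ord]
    ## residual min/max achievable mass from level i..n
    minRest <- rev(cumsum(rev(mass * mn)))
    maxRest <- rev(cumsum(rev(mass * mx)))
    minRest <- c(minRest, 0)
    maxRest <- c(maxRest, 0)
    hits <- list()
    counts <- integer(n)
    recurse <- function(level, acc) {
        if (level > n) {
            if (acc >= lo && acc <= hi)
                hits[[length(hits) + 1L]] <<- c(counts, acc)
            return(invisible())
        }
        for (k in mn[level]:mx[level]) {
            acc2 <- acc + k * mass[level]
            if (acc2 + minRest[level + 1L] > hi) break
            if (acc2 + maxRest[level + 1L] < lo) next
            counts[level] <<- k
            recurse(level + 1L, acc2)
        }
        counts[level] <<- mn[level]
        invisible()
    }
    recurse(1L, 0)
    out <- matrix(0, nrow = length(hits), ncol = n + 1L)
    for (i in seq_along(hits)) out[i, ] <- hits[[i]]
    ## back to table order
    df <- as.data.frame(out[, order(ord), drop = FALSE])
    names(df) <- table$name
    df$mass <- if (length(hits)) out[, n + 1L] else numeric(0)
    df$delta <- df$mass - queryMass
    o <- do.call(order, c(list(abs(df$delta)),
                          as.list(df[, table$name, drop = FALSE])))
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Attach glycan composition candidates to a decomposed pair
#'
#' Reads the glycan moiety mass from the pair's glycan spectrum metadata,
#' enumerates matching compositions and returns a reporting record.
#'
#' @param pair A [DecomposedPair-class] whose glycan spectrum carries
#'   `glycanMoietyMass` metadata.
#' @param table Monosaccharide residue mass table with bounds.
#' @param tolerance Mass tolerance in Da (default 0.1).
#' @return A list with `sourceId`, `glycanMoietyMass`, `compositions`
#'   (the [generateCompositions()] table) and `noComposition` (flag set
#'   when no composition fits).
#' @export
compositionsForPair <- function(pair, table = monosaccharideTable(),
                                tolerance = 0.1) {
    stopifnot(is(pair, "DecomposedPair"))
    mass <- spectrumMetadata(glycanSpectrum(pair))$glycanMoietyMass
    if (is.null(mass))
        stop("pair carries no glycanMoietyMass metadata")
    comps <- generateCompositions(mass, table, tolerance)
    list(sourceId = sourceId(pair), glycanMoietyMass = mass,
         compositions = comps, noComposition = nrow(comps) == 0L)
}
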