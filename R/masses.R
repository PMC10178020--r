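#' @title Monoisotopic mass constants and mass arithmetic
#'
#' @description Single source of truth for the monoisotopic masses used
#' throughout the package: elements, amino-acid residues, monosaccharide
#' residues, the diagnostic oxonium-ion m/z table, and the N-glycan core
#' Y-ion pattern offset template.
#'
#' Two mass scales coexist deliberately. The monosaccharide residue masses
#' used for glycan composition arithmetic ([glycanMass()]) and for the
#' pattern offsets are the four-to-five decimal constants of the default
#' configuration, used verbatim so that a run of this package reproduces
#' that configuration bit for bit. Oxonium m/z values, in contrast, can be
#' recomputed from first principles ([oxoniumMz()]) using monoisotopic
#' element masses, which reproduces the configured six-ion table to six
#' decimal places (the HexNAc entry is tabulated at four decimals; the
#' HexHexNAcdHex entry is tabulated ~0.55 mDa above its theoretical value
#' and is kept verbatim).
#'
#' @name masses
NULL

## CODATA proton; monoisotopic water (2H + O)
.protonMass <- 1.00727646
.waterMass <- 18.0105646

#' Monoisotopic element masses
#'
#' @return Named numeric vector of monoisotopic masses (Da) for C, H, N, O,
#'   S, plus the proton.
#' @examples
#' elementMasses()[["H"]]
#' @export
elementMasses <- function() {
    c(C = 12.0, H = 1.00782503, N = 14.0030740, O = 15.9949146,
      S = 31.9720707, proton = .protonMass)
}

#' Proton and water monoisotopic masses
#'
#' @return Mass in Da.
#' @export
protonMass <- function() .protonMass

#' @rdname protonMass
#' @export
waterMass <- function() .waterMass

## Elemental composition of a monosaccharide *residue* (after loss of water
## on glycosidic bond formation): Hex C6H10O5, HexNAc C8H13NO5,
## dHex C6H10O4, NeuAc C11H17NO8.
.monosaccharideFormulas <- list(
    Hex    = c(C = 6,  H = 10, N = 0, O = 5),
    HexNAc = c(C = 8,  H = 13, N = 1, O = 5),
    dHex   = c(C = 6,  H = 10, N = 0, O = 4),
    NeuAc  = c(C = 11, H = 17, N = 1, O = 8)
)

.formulaMass <- function(formula) {
    el <- elementMasses()
    sum(formula * el[names(formula)])
}

#' Monosaccharide residue mass table with composition bounds
#'
#' The residue masses and per-monosaccharide count bounds used by the
#' glycan composition generator. Defaults are the standard configuration:
#' Hex 162.05282, HexNAc 203.07937, dHex 146.05791, NeuAc 291.09542, with
#' bounds Hex 0--12, HexNAc 1--7, dHex 0--3, NeuAc 0--4 (N-glycans carry at
#' least the proximal HexNAc).
#'
#' @return A data.frame with columns `name`, `mass` (Da), `min`, `max`.
#' @examples
#' monosaccharideTable()
#' @export
monosaccharideTable <- function() {
    data.frame(
        name = c("Hex", "HexNAc", "dHex", "NeuAc"),
        mass = c(162.05282, 203.07937, 146.05791, 291.09542),
        min = c(0L, 1L, 0L, 0L),
        max = c(12L, 7L, 3L, 4L),
        stringsAsFactors = FALSE
    )
}

.checkMonosaccharideTable <- function(table) {
    stopifnot(is.data.frame(table),
              all(c("name", "mass", "min", "max") %in% names(table)))
    if (any(table$min < 0) || any(table$max < table$min))
        stop("monosaccharide bounds must satisfy 0 <= min <= max")
    if (any(table$mass <= 0))
        stop("monosaccharide residue masses must be positive")
    invisible(table)
}

#' Diagnostic oxonium ion m/z table
#'
#' The six-ion production list used by the glycopeptide filter:
#' HexHexNAc 366.139472, HexHexNAcNeuAc 657.234889, HexHexNAcdHex
#' 512.19793, NeuAc 292.102693, NeuAc-H2O 274.092128, HexNAc 204.0867.
#'
#' @return A data.frame with columns `name` and `mz` (Da, singly
#'   protonated).
#' @examples
#' oxoniumTable()
#' @export
oxoniumTable <- function() {
    data.frame(
        name = c("HexHexNAc", "HexHexNAcNeuAc", "HexHexNAcdHex",
                 "NeuAc", "NeuAc-H2O", "HexNAc"),
        mz = c(366.139472, 657.234889, 512.19793,
               292.102693, 274.092128, 204.0867),
        stringsAsFactors = FALSE
    )
}

#' N-glycan core Y-ion pattern offset template
#'
#' Signed mass offsets (Da) of the eight-peak core fragmentation pattern
#' relative to the reference peak, the singly protonated peptide + HexNAc
#' ion (Y1, offset 0). Negative offsets are the deglycosylated peptide
#' (Y0, -203.0794), a peak 17.0027 Da below Y0 attributed to loss at the
#' glycosylated asparagine (-220.0821), and the cross-ring fragment of the
#' proximal HexNAc (-120.0423). Positive offsets climb the core:
#' +HexNAc (Y2), then +Hex, +2Hex, +3Hex.
#'
#' @return Strictly increasing numeric vector of length 8 containing 0.
#' @examples
#' patternTemplate()
#' @export
patternTemplate <- function() {
    c(-220.0821, -203.0794, -120.0423, 0, 203.0794, 365.1322,
      527.185, 689.2378)
}

## Standard monoisotopic amino-acid residue masses (free termini add water).
.aaResidueMasses <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
    V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
    I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
    K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
    F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Neutral monoisotopic mass of a peptide
#'
#' Sums standard monoisotopic residue masses and adds one water for the
#' free termini. Only the 20 standard one-letter codes are accepted.
#'
#' @param sequence Amino-acid sequence, one-letter codes. The empty string
#'   yields the mass of water.
#' @return Neutral mass in Da.
#' @examples
#' peptideNeutralMass("GGGNK")  # lightest tryptic N-glycopeptide, ~431 Da
#' @export
peptideNeutralMass <- function(sequence) {
    stopifnot(is.character(sequence), length(sequence) == 1L,
              !is.na(sequence))
    if (nchar(sequence) == 0L)
        return(.waterMass)
    letters1 <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    masses <- .aaResidueMasses[letters1]
    if (anyNA(masses)) {
        bad <- which(is.na(masses))[1L]
        stop(sprintf("unknown amino-acid residue '%s' at position %d",
                     letters1[bad], bad))
    }
    sum(masses) + .waterMass
}

.normalizeComposition <- function(composition, table = monosaccharideTable()) {
    if (is.list(composition))
        composition <- unlist(composition)
    if (length(composition) == 0L)
        return(stats::setNames(numeric(length(table$name)), table$name))
    if (is.null(names(composition)) || any(!nzchar(names(composition))))
        stop("composition must be a named count vector")
    unknown <- setdiff(names(composition), table$name)
    if (length(unknown))
        stop("unknown monosaccharide(s): ", paste(unknown, collapse = ", "))
    out <- stats::setNames(numeric(length(table$name)), table$name)
    out[names(composition)] <- composition
    if (any(out < 0))
        stop("monosaccharide counts must be non-negative")
    out
}

#' Neutral mass of a glycan composition
#'
#' Dot product of monosaccharide counts with the residue masses of
#' [monosaccharideTable()]. The all-zero composition has mass 0.
#'
#' @param composition Named integer vector or list of counts, e.g.
#'   `c(Hex = 5, HexNAc = 4, NeuAc = 2)`. Counts must be non-negative.
#' @param table Monosaccharide residue mass table.
#' @return Neutral mass in Da.
#' @examples
#' glycanMass(c(HexNAc = 1))
#' glycanMass(c(Hex = 5, HexNAc = 4, NeuAc = 2))
#' @export
glycanMass <- function(composition, table = monosaccharideTable()) {
    counts <- .normalizeComposition(composition, table)
    sum(counts * table$mass[match(names(counts), table$name)])
}

#' Theoretical oxonium ion m/z from elemental masses
#'
#' Computes the singly protonated m/z of a B-type glycan fragment from
#' monoisotopic element masses: the sum of residue masses of the
#' constituent monosaccharides, minus any additional water losses, plus a
#' proton. Reproduces the configured six-ion table from first principles
#' (see [masses] for the two tabulated exceptions).
#'
#' @param composition Named count vector of monosaccharides; must be
#'   non-empty with a positive total count.
#' @param waterLosses Number of additional water losses (default 0).
#' @return m/z in Da.
#' @examples
#' oxoniumMz(c(Hex = 1, HexNAc = 1))        # 366.139472
#' oxoniumMz(c(NeuAc = 1), waterLosses = 1) # 274.092128
#' @export
oxoniumMz <- function(composition, waterLosses = 0) {
    counts <- .normalizeComposition(composition)
    if (sum(counts) <= 0)
        stop("oxonium composition must contain at least one monosaccharide")
    stopifnot(waterLosses >= 0)
    residues <- vapply(.monosaccharideFormulas, .formulaMass, numeric(1L))
    sum(counts * residues[names(counts)]) - waterLosses * .waterMass +
        .protonMass
}
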