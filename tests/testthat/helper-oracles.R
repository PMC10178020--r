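# Independent oracles used across the suite. These never call the code
# paths they check.

# Monoisotopic element masses (CODATA / IUPAC)
el <- c(C = 12.0, H = 1.00782503, N = 14.0030740, O = 15.9949146,
        S = 31.9720707)
oracleProton <- 1.00727646
oracleWater <- 2 * el[["H"]] + el[["O"]]

# Amino-acid residue elemental compositions (C, H, N, O, S)
aaFormulas <- list(
    G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)

# peptide neutral mass by elemental summation (residue formulas + water)
oraclePeptideMass <- function(sequence) {
    if (nchar(sequence) == 0L) return(oracleWater)
    aa <- strsplit(sequence, "")[[1]]
    counts <- Reduce(`+`, aaFormulas[aa])
    sum(counts * el[c("C", "H", "N", "O", "S")]) + oracleWater
}

# monosaccharide residue masses from elemental composition
oracleResidue <- c(
    Hex    = 6 * el[["C"]] + 10 * el[["H"]] + 5 * el[["O"]],
    HexNAc = 8 * el[["C"]] + 13 * el[["H"]] + el[["N"]] + 5 * el[["O"]],
    dHex   = 6 * el[["C"]] + 10 * el[["H"]] + 4 * el[["O"]],
    NeuAc  = 11 * el[["C"]] + 17 * el[["H"]] + el[["N"]] + 8 * el[["O"]]
)

# brute-force glycan composition enumeration: four nested loops over the
# bounds, no pruning; returns "Hex.HexNAc.dHex.NeuAc" keys
bruteForceCompositions <- function(queryMass, table = monosaccharideTable(),
                                   tolerance = 0.1) {
    i <- function(nm) match(nm, table$name)
    keys <- character(0)
    for (h in table$min[i("Hex")]:table$max[i("Hex")])
    for (n in table$min[i("HexNAc")]:table$max[i("HexNAc")])
    for (d in table$min[i("dHex")]:table$max[i("dHex")])
    for (s in table$min[i("NeuAc")]:table$max[i("NeuAc")]) {
        mass <- h * table$mass[i("Hex")] + n * table$mass[i("HexNAc")] +
            d * table$mass[i("dHex")] + s * table$mass[i("NeuAc")]
        if (abs(mass - queryMass) <= tolerance)
            keys <- c(keys, paste(h, n, d, s, sep = "."))
    }
    sort(keys)
}

compositionKeys <- function(df) {
    if (nrow(df) == 0L) return(character(0))
    sort(paste(df$Hex, df$HexNAc, df$dHex, df$NeuAc, sep = "."))
}

# a minimal spectrum builder for hand-made fixtures
makeSpec <- function(mz, intensity, precursorMz = 2000, charge = 2L,
                     peakCharge = NA_integer_, id = "fix") {
    Spectrum(id, precursorMz, charge, mz, intensity, peakCharge)
}
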