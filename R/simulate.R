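#' Simulation parameters
#'
#' Controls for the synthetic spectrum generator. Defaults emulate a
#' reasonably noisy but well-fragmented glycopeptide CID spectrum:
#'
#' @param ladderCompleteness Probability that each non-reference core
#'   pattern peak is present (default 0.9; the Y1 reference is always
#'   emitted).
#' @param byCoverage Probability that each b/y (and b/y + HexNAc) ion is
#'   present (default 0.7).
#' @param oxoniumIntensityFraction Target fraction of total spectrum
#'   intensity carried by oxonium peaks (default 0.05; well above the
#'   0.0047 classification threshold, as observed for genuine glycopeptide
#'   spectra).
#' @param nNoisePeaks Number of uniform random noise peaks (default 30).
#' @param noiseMzRange m/z range for noise peaks, or `NULL` for the
#'   per-spectrum default `(200, precursorMz * charge)`.
#' @param seed Integer seed fixing the full output, or `NA` to use the
#'   current RNG state.
#' @return Named list of parameters.
#' @export
simParams <- function(ladderCompleteness = 0.9, byCoverage = 0.7,
                      oxoniumIntensityFraction = 0.05, nNoisePeaks = 30L,
                      noiseMzRange = NULL, seed = NA_integer_) {
    stopifnot(ladderCompleteness >= 0, ladderCompleteness <= 1,
              byCoverage >= 0, byCoverage <= 1,
              oxoniumIntensityFraction >= 0, oxoniumIntensityFraction < 1,
              nNoisePeaks >= 0)
    list(ladderCompleteness = ladderCompleteness, byCoverage = byCoverage,
         oxoniumIntensityFraction = oxoniumIntensityFraction,
         nNoisePeaks = as.integer(nNoisePeaks),
         noiseMzRange = noiseMzRange, seed = seed)
}

## first N-X(not P)-S/T sequon, else first N, else the middle residue
.glycositeIndex <- function(peptide) {
    aa <- strsplit(peptide, "", fixed = TRUE)[[1L]]
    n <- length(aa)
    for (i in seq_len(n - 2L)) {
        if (aa[i] == "N" && aa[i + 1L] != "P" &&
            aa[i + 2L] %in% c("S", "T"))
            return(i)
    }
    if (any(aa == "N")) return(which(aa == "N")[1L])
    as.integer(ceiling(n / 2))
}

## b/y fragment m/z (1+) and whether each fragment spans the glycosite
.byIons <- function(peptide, site) {
    aa <- strsplit(peptide, "", fixed = TRUE)[[1L]]
    res <- .aaResidueMasses[aa]
    n <- length(aa)
    i <- seq_len(n - 1L)
    b <- cumsum(res)[i] + .protonMass
    y <- rev(cumsum(rev(res)))[i + 1L] + .waterMass + .protonMass
    list(mz = c(b, y),
         hasSite = c(i >= site, i < site),  # y_i spans residues (i+1)..n
         label = c(paste0("b", i), paste0("y", n - i)))
}

.logUniform <- function(n, lo, hi) 10^stats::runif(n, lo, hi)

## oxonium ions implied by a composition (names from oxoniumTable())
.impliedOxonium <- function(composition) {
    tab <- oxoniumTable()
    counts <- .normalizeComposition(composition)
    want <- c("HexNAc",
              if (counts[["Hex"]] >= 1) "HexHexNAc",
              if (counts[["NeuAc"]] >= 1) c("NeuAc", "NeuAc-H2O"),
              if (counts[["Hex"]] >= 1 && counts[["NeuAc"]] >= 1)
                  "HexHexNAcNeuAc",
              if (counts[["Hex"]] >= 1 && counts[["dHex"]] >= 1)
                  "HexHexNAcdHex")
    tab[tab$name %in% want, , drop = FALSE]
}

#' Simulate a glycopeptide fragmentation spectrum with ground truth
#'
#' Emits the peak classes of a CID N-glycopeptide spectrum: the oxonium
#' ions implied by the glycan composition (HexNAc always; Hex- and
#' NeuAc-derived ions only when the composition contains those residues),
#' the eight-peak core Y-ion pattern at its true positions anchored on Y1
#' (each non-reference peak kept with probability `ladderCompleteness`;
#' ladder steps that would exceed the precursor mass are omitted), b/y and
#' b/y + HexNAc ions at probability `byCoverage` (the + HexNAc series only
#' for fragments spanning the glycosylation site), and uniform noise
#' peaks. Fragment intensities are log-uniform with the Y1 peak biased to
#' be among the most intense, as observed in real spectra. Fully
#' reproducible from `params$seed`.
#'
#' @param peptide Amino-acid sequence (length >= 5). The glycosylation
#'   site is the first N-X(not P)-S/T sequon when present.
#' @param composition Named monosaccharide count vector within the default
#'   bounds.
#' @param charge Precursor charge (default 2).
#' @param params See [simParams()].
#' @return A list with `spectrum` ([Spectrum-class]) and `truth` (list
#'   with `peptide`, `composition`, `charge`, `trueY1Mz`,
#'   `trueGlycanMass`, `label`).
#' @examples
#' sim <- simulateGlycopeptide("EEQYNSTYR", c(Hex = 5, HexNAc = 4),
#'                             params = simParams(seed = 1))
#' sim$spectrum
#' @export
simulateGlycopeptide <- function(peptide, composition, charge = 2L,
                                 params = simParams()) {
    stopifnot(nchar(peptide) >= 5L, charge >= 1L)
    tab <- monosaccharideTable()
    counts <- .normalizeComposition(composition, tab)
    bad <- counts < tab$min[match(names(counts), tab$name)] |
        counts > tab$max[match(names(counts), tab$name)]
    if (any(bad))
        stop("composition outside default bounds: ",
             paste(names(counts)[bad], collapse = ", "))
    if (!is.na(params$seed)) set.seed(params$seed)
    hexnac <- tab$mass[tab$name == "HexNAc"]
    p <- peptideNeutralMass(peptide)
    G <- glycanMass(counts, tab)
    M <- p + G
    precMz <- M / charge + .protonMass
    y1 <- p + hexnac + .protonMass
    ## core pattern
    offsets <- patternTemplate()
    ladder <- y1 + offsets
    keepL <- offsets == 0 |
        (stats::runif(length(offsets)) <= params$ladderCompleteness)
    keepL <- keepL & ladder <= M + .protonMass + 0.5 & ladder > 0
    ladderMz <- ladder[keepL]
    ladderInt <- .logUniform(length(ladderMz), 1.8, 2.8)
    ladderInt[ladder[keepL] == y1] <- .logUniform(1L, 2.9, 3.05)
    ## b/y ions (and +HexNAc for site-spanning fragments)
    site <- .glycositeIndex(peptide)
    frag <- .byIons(peptide, site)
    byMz <- c(frag$mz, frag$mz[frag$hasSite] + hexnac)
    keepB <- stats::runif(length(byMz)) <= params$byCoverage
    byMz <- byMz[keepB]
    byInt <- .logUniform(length(byMz), 1.5, 2.8)
    ## noise
    rng <- params$noiseMzRange
    if (is.null(rng)) rng <- c(200, precMz * charge)
    noiseMz <- stats::runif(params$nNoisePeaks, rng[1L], rng[2L])
    noiseInt <- .logUniform(params$nNoisePeaks, 1.3, 2.4)
    ## oxonium ions scaled to the target fraction of total intensity
    oxo <- .impliedOxonium(counts)
    otherTotal <- sum(ladderInt, byInt, noiseInt)
    f <- params$oxoniumIntensityFraction
    w <- .logUniform(nrow(oxo), 0, 1)
    oxoInt <- w / sum(w) * f / (1 - f) * otherTotal
    spec <- Spectrum(
        id = sprintf("sim|%s|%s|%d", peptide,
                     paste0(tab$name, counts[tab$name], collapse = ""),
                     charge),
        precursorMz = precMz, precursorCharge = as.integer(charge),
        mz = c(ladderMz, byMz, noiseMz, oxo$mz),
        intensity = c(ladderInt, byInt, noiseInt, oxoInt),
        charge = 1L)
    truth <- list(peptide = peptide, composition = counts,
                  charge = as.integer(charge), trueY1Mz = y1,
                  trueGlycanMass = G, label = "glyco")
    list(spectrum = spec, truth = truth)
}

#' Simulate a non-glycopeptide fragmentation spectrum
#'
#' b/y ions plus noise only. Every peak (fragment or noise) that would
#' fall within 0.02 Da of an oxonium table m/z is displaced just outside
#' the window, so the negatives are clean by construction: no peak of a
#' simulated non-glycopeptide can ever satisfy the oxonium filter.
#'
#' @inheritParams simulateGlycopeptide
#' @return As [simulateGlycopeptide()], with `label = "non-glyco"` and
#'   `NA` truth masses.
#' @export
simulateNonglyco <- function(peptide, charge = 2L, params = simParams()) {
    stopifnot(nchar(peptide) >= 5L, charge >= 1L)
    if (!is.na(params$seed)) set.seed(params$seed)
    p <- peptideNeutralMass(peptide)
    precMz <- p / charge + .protonMass
    frag <- .byIons(peptide, .glycositeIndex(peptide))
    keepB <- stats::runif(length(frag$mz)) <= params$byCoverage
    byMz <- frag$mz[keepB]
    byInt <- .logUniform(length(byMz), 1.5, 3)
    rng <- params$noiseMzRange
    if (is.null(rng)) rng <- c(200, max(precMz * charge, 300))
    noiseMz <- stats::runif(params$nNoisePeaks, rng[1L], rng[2L])
    noiseInt <- .logUniform(params$nNoisePeaks, 1.3, 2.4)
    mz <- c(byMz, noiseMz)
    ## displace anything inside an oxonium window
    oxo <- oxoniumTable()$mz
    for (i in seq_along(mz)) {
        while (any(abs(mz[i] - oxo) <= 0.025))
            mz[i] <- mz[i] + 0.06
    }
    spec <- Spectrum(id = sprintf("sim|%s||%d", peptide, charge),
                     precursorMz = precMz,
                     precursorCharge = as.integer(charge),
                     mz = mz, intensity = c(byInt, noiseInt), charge = 1L)
    truth <- list(peptide = peptide, composition = NULL,
                  charge = as.integer(charge), trueY1Mz = NA_real_,
                  trueGlycanMass = NA_real_, label = "non-glyco")
    list(spectrum = spec, truth = truth)
}

#' Default simulation pools
#'
#' Sequon-bearing tryptic glycopeptides (including well-characterized
#' plasma glycopeptides), plasma-like N-glycan compositions (complex di-
#' and tri-antennary, fucosylated and high-mannose species), and
#' sequon-free tryptic peptides for the negative class.
#'
#' @return Named list with `glycoPeptides`, `compositions` (list of named
#'   count vectors), `nonGlycoPeptides`.
#' @export
simulationPools <- function() {
    list(
        glycoPeptides = c(
            "SVQEIQATFFYFTPNK",
            "VVLHPNYSQVDIGIK",
            "SLGNVNFTVSAEALESQELCGTEVPSVPEHGR",
            "GLTFQQNASSMCVPDQDTAIR",
            "EEQYNSTYR",
            "EEQFNSTFR",
            "LGACNDTLQQLMEVFK",
            "VSNQTLSLFFTVLQDVPVR"
        ),
        compositions = list(
            c(Hex = 5, HexNAc = 4, NeuAc = 2),
            c(Hex = 5, HexNAc = 4, NeuAc = 1),
            c(Hex = 5, HexNAc = 4),
            c(Hex = 5, HexNAc = 4, dHex = 1, NeuAc = 1),
            c(Hex = 5, HexNAc = 4, dHex = 1, NeuAc = 2),
            c(Hex = 5, HexNAc = 2),
            c(Hex = 6, HexNAc = 2),
            c(Hex = 6, HexNAc = 5, NeuAc = 3),
            c(Hex = 4, HexNAc = 4, dHex = 1),
            c(Hex = 3, HexNAc = 4, dHex = 1)
        ),
        nonGlycoPeptides = c(
            "AGFAGDDAPR",
            "GYSFTTTAER",
            "VAPEEHPVLLTEAPLNPK",
            "DSYVGDEAQSK",
            "IWHHTFYNELR",
            "LDLAGRDLTDYLMK",
            "YPIEHGIVTNWDDMEK",
            "SYELPDGQVITIGNER"
        )
    )
}

#' Simulate a labelled cohort of spectra
#'
#' Samples peptides, compositions and charges from the pools, simulates
#' `nGlyco` glycopeptide and `nNonglyco` non-glycopeptide spectra, and
#' either returns them in memory or writes an MGF plus a tab-separated
#' ground-truth table.
#'
#' @param nGlyco,nNonglyco Numbers of spectra per class.
#' @param params See [simParams()]; `params$seed` fixes the sampling and
#'   every spectrum.
#' @param pools See [simulationPools()].
#' @param charges Charge states sampled uniformly (default 2:3).
#' @param outPrefix If non-`NULL`, write `<prefix>.mgf` and
#'   `<prefix>_truth.tsv` and include their paths in the result.
#' @return List with `spectra` (list of [Spectrum-class]), `truth`
#'   (data.frame with one row per spectrum: id, label, peptide,
#'   composition, charge, trueY1Mz, trueGlycanMass) and, when written,
#'   `spectraPath`/`truthPath`.
#' @export
simulateCohort <- function(nGlyco, nNonglyco, params = simParams(),
                           pools = simulationPools(), charges = 2:3,
                           outPrefix = NULL) {
    stopifnot(nGlyco >= 0, nNonglyco >= 0,
              length(pools$glycoPeptides) > 0,
              length(pools$compositions) > 0,
              length(pools$nonGlycoPeptides) > 0)
    if (!is.na(params$seed)) set.seed(params$seed)
    innerParams <- params
    innerParams$seed <- NA_integer_  # one stream for the whole cohort
    spectra <- vector("list", nGlyco + nNonglyco)
    rows <- vector("list", nGlyco + nNonglyco)
    compName <- function(cmp) {
        nz <- cmp[cmp > 0]
        paste0(names(nz), nz, collapse = "")
    }
    for (i in seq_len(nGlyco)) {
        pep <- sample(pools$glycoPeptides, 1L)
        cmp <- pools$compositions[[sample(length(pools$compositions), 1L)]]
        z <- sample(charges, 1L)
        sim <- simulateGlycopeptide(pep, cmp, z, innerParams)
        sim$spectrum@id <- sprintf("glyco_%04d|%s|%s|%d", i, pep,
                                   compName(cmp), z)
        spectra[[i]] <- sim$spectrum
        rows[[i]] <- data.frame(
            id = spectrumId(sim$spectrum), label = "glyco", peptide = pep,
            composition = compName(cmp), charge = z,
            trueY1Mz = sim$truth$trueY1Mz,
            trueGlycanMass = sim$truth$trueGlycanMass,
            stringsAsFactors = FALSE)
    }
    for (j in seq_len(nNonglyco)) {
        pep <- sample(pools$nonGlycoPeptides, 1L)
        z <- sample(charges, 1L)
        sim <- simulateNonglyco(pep, z, innerParams)
        i <- nGlyco + j
        sim$spectrum@id <- sprintf("nonglyco_%04d|%s|%d", j, pep, z)
        spectra[[i]] <- sim$spectrum
        rows[[i]] <- data.frame(
            id = spectrumId(sim$spectrum), label = "non-glyco",
            peptide = pep, composition = "", charge = z,
            trueY1Mz = NA_real_, trueGlycanMass = NA_real_,
            stringsAsFactors = FALSE)
    }
    truth <- if (length(rows)) do.call(rbind, rows)
             else data.frame(id = character(0), label = character(0),
                             peptide = character(0),
                             composition = character(0),
                             charge = integer(0), trueY1Mz = numeric(0),
                             trueGlycanMass = numeric(0))
    out <- list(spectra = spectra, truth = truth)
    if (!is.null(outPrefix)) {
        spectraPath <- paste0(outPrefix, ".mgf")
        truthPath <- paste0(outPrefix, "_truth.tsv")
        writeSpectra(spectra, spectraPath, format = "mgf")
        utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        out$spectraPath <- spectraPath
        out$truthPath <- truthPath
    }
    out
}
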