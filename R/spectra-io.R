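#' Read MS/MS spectra from an MGF or ms2 peak list
#'
#' Supported dialects:
#' \itemize{
#'   \item MGF: `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS`
#'     (m/z, optional intensity), `CHARGE` (e.g. `2+`), and peak lines
#'     `mz intensity [charge]`.
#'   \item ms2: `S` scan lines carrying the precursor m/z, `Z` lines with
#'     charge and singly protonated mass, and `mz intensity` peak lines.
#' }
#'
#' @param path Input file path.
#' @param format `"auto"` (by file extension), `"mgf"` or `"ms2"`.
#' @return List of [Spectrum-class] objects in file order, each with peaks
#'   sorted ascending by m/z.
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(path, format = c("auto", "mgf", "ms2")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, mgf = "mgf", ms2 = "ms2",
                         stop("cannot infer format from extension '", ext,
                              "'; pass format explicitly"))
    }
    if (!file.exists(path))
        stop("cannot read spectra: file not found: ", path)
    switch(format, mgf = .readMgf(path), ms2 = .readMs2(path))
}

#' Write MS/MS spectra to an MGF or ms2 peak list
#'
#' @param spectra List of [Spectrum-class] objects.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"mgf"` or `"ms2"`.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(spectra, path, format = c("auto", "mgf", "ms2")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, mgf = "mgf", ms2 = "ms2",
                         stop("cannot infer format from extension '", ext,
                              "'; pass format explicitly"))
    }
    if (is(spectra, "Spectrum")) spectra <- list(spectra)
    switch(format, mgf = .writeMgf(spectra, path),
           ms2 = .writeMs2(spectra, path))
    invisible(path)
}

.readMgf <- function(path) {
    lines <- readLines(path, warn = FALSE)
    spectra <- list()
    inBlock <- FALSE
    title <- NA_character_
    pmz <- NA_real_
    pz <- NA_integer_
    mz <- numeric(0); int <- numeric(0); z <- integer(0)
    nblock <- 0L
    for (i in seq_along(lines)) {
        line <- trimws(lines[i])
        if (!nzchar(line) || startsWith(line, "#")) next
        if (line == "BEGIN IONS") {
            if (inBlock)
                stop("malformed MGF (nested BEGIN IONS) at line ", i)
            inBlock <- TRUE
            nblock <- nblock + 1L
            title <- paste0("spectrum_", nblock)
            pmz <- NA_real_; pz <- NA_integer_
            mz <- numeric(0); int <- numeric(0); z <- integer(0)
        } else if (line == "END IONS") {
            if (!inBlock)
                stop("malformed MGF (END IONS without BEGIN) at line ", i)
            if (is.na(pmz))
                stop("MGF record '", title, "' ending at line ", i,
                     " has no PEPMASS")
            spectra[[length(spectra) + 1L]] <-
                Spectrum(title, pmz, pz, mz, int, z)
            inBlock <- FALSE
        } else if (inBlock && grepl("=", line, fixed = TRUE)) {
            key <- toupper(sub("=.*$", "", line))
            value <- sub("^[^=]*=", "", line)
            if (key == "TITLE") title <- value
            else if (key == "PEPMASS")
                pmz <- as.numeric(strsplit(trimws(value), "[ \t]+")[[1L]][1L])
            else if (key == "CHARGE")
                pz <- as.integer(sub("\\+$", "", trimws(value)))
            ## other headers ignored
        } else if (inBlock) {
            fields <- strsplit(line, "[ \t]+")[[1L]]
            if (length(fields) < 2L)
                stop("malformed MGF peak line in record '", title,
                     "' at line ", i, ": ", line)
            v <- suppressWarnings(as.numeric(fields))
            if (anyNA(v[1:2]))
                stop("non-numeric MGF peak line in record '", title,
                     "' at line ", i, ": ", line)
            mz <- c(mz, v[1L]); int <- c(int, v[2L])
            z <- c(z, if (length(fields) >= 3L) as.integer(v[3L])
                      else NA_integer_)
        } else {
            stop("unexpected content outside BEGIN IONS/END IONS at line ",
                 i, ": ", line)
        }
    }
    if (inBlock)
        stop("malformed MGF: unterminated record '", title, "'")
    spectra
}

.writeMgf <- function(spectra, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (s in spectra) {
        stopifnot(is(s, "Spectrum"))
        p <- peaks(s)
        header <- c("BEGIN IONS",
                    paste0("TITLE=", spectrumId(s)),
                    paste0("PEPMASS=", sprintf("%.6f", precursorMz(s))))
        if (!is.na(precursorCharge(s)))
            header <- c(header,
                        paste0("CHARGE=", precursorCharge(s), "+"))
        body <- ifelse(is.na(p$charge),
                       sprintf("%.6f %.4f", p$mz, p$intensity),
                       sprintf("%.6f %.4f %d", p$mz, p$intensity, p$charge))
        writeLines(c(header, body, "END IONS", ""), con)
    }
}

.readMs2 <- function(path) {
    lines <- readLines(path, warn = FALSE)
    spectra <- list()
    id <- NULL
    pmz <- NA_real_; pz <- NA_integer_
    mz <- numeric(0); int <- numeric(0)
    flush <- function() {
        if (is.null(id)) return()
        spectra[[length(spectra) + 1L]] <<-
            Spectrum(id, pmz, pz, mz, int, NA_integer_)
    }
    for (i in seq_along(lines)) {
        line <- trimws(lines[i])
        if (!nzchar(line) || startsWith(line, "H")) next
        fields <- strsplit(line, "[ \t]+")[[1L]]
        if (fields[1L] == "S") {
            if (length(fields) < 4L)
                stop("malformed ms2 S line at line ", i, ": ", line)
            flush()
            id <- paste0("scan_", fields[2L])
            pmz <- as.numeric(fields[4L])
            pz <- NA_integer_
            mz <- numeric(0); int <- numeric(0)
        } else if (fields[1L] == "Z") {
            if (is.null(id) || length(fields) < 3L)
                stop("malformed ms2 Z line at line ", i, ": ", line)
            pz <- as.integer(fields[2L])
        } else {
            if (is.null(id))
                stop("ms2 peak line before any S line at line ", i)
            v <- suppressWarnings(as.numeric(fields[1:2]))
            if (anyNA(v))
                stop("non-numeric ms2 peak line at line ", i, ": ", line)
            mz <- c(mz, v[1L]); int <- c(int, v[2L])
        }
    }
    flush()
    spectra
}

.writeMs2 <- function(spectra, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines("H\tCreationTool\tGlycoDecomposer", con)
    for (i in seq_along(spectra)) {
        s <- spectra[[i]]
        stopifnot(is(s, "Spectrum"))
        z <- precursorCharge(s)
        if (is.na(z)) z <- 1L
        mh <- (precursorMz(s) - .protonMass) * z + .protonMass
        writeLines(sprintf("S\t%d\t%d\t%.6f", i, i, precursorMz(s)), con)
        writeLines(sprintf("Z\t%d\t%.6f", z, mh), con)
        p <- peaks(s)
        writeLines(sprintf("%.6f %.4f", p$mz, p$intensity), con)
    }
}

#' Apply the global minimum-intensity prefilter
#'
#' Retains exactly the peaks with intensity greater than or equal to the
#' threshold (inclusive). All downstream stages operate on the prefiltered
#' spectrum.
#'
#' @param spectrum A [Spectrum-class].
#' @param minIntensity Intensity threshold (>= 0); default 15 counts.
#' @return The filtered [Spectrum-class] (possibly with zero peaks).
#' @export
prefilterPeaks <- function(spectrum, minIntensity = 15) {
    stopifnot(is(spectrum, "Spectrum"), minIntensity >= 0)
    p <- peaks(spectrum)
    .withPeaks(spectrum, p[p$intensity >= minIntensity, , drop = FALSE])
}

#' Neutral mass of the precursor
#'
#' `M = precursorMz * z - z * proton` for precursor charge `z`.
#'
#' @param spectrum A [Spectrum-class] with known precursor charge.
#' @return Neutral monoisotopic mass in Da.
#' @export
precursorNeutralMass <- function(spectrum) {
    stopifnot(is(spectrum, "Spectrum"))
    z <- precursorCharge(spectrum)
    if (is.na(z) || z < 1L)
        stop("precursor charge unknown for spectrum '",
             spectrumId(spectrum), "'; cannot compute neutral mass")
    (precursorMz(spectrum) - .protonMass) * z
}

#' Charge-deconvolute a spectrum to singly protonated m/z
#'
#' Every peak with an annotated charge z > 1 is replaced by its singly
#' protonated equivalent, `mz' = mz * z - (z - 1) * proton`, and its charge
#' set to 1. Peaks with unknown charge are treated as already singly
#' charged (inputs are assumed decharged; annotations are advisory).
#' Deconvoluted peaks that land within `mergeTolerance` of one another are
#' merged: intensities are summed and the merged m/z is the
#' intensity-weighted mean. The operation is idempotent.
#'
#' @param spectrum A [Spectrum-class].
#' @param mergeTolerance m/z window for merging duplicates (Da).
#' @return The deconvoluted [Spectrum-class], all peak charges 1 or `NA`.
#' @export
chargeDeconvolute <- function(spectrum, mergeTolerance = 0.001) {
    stopifnot(is(spectrum, "Spectrum"), mergeTolerance > 0)
    p <- peaks(spectrum)
    if (nrow(p) == 0L)
        return(spectrum)
    multi <- !is.na(p$charge) & p$charge > 1L
    if (any(multi)) {
        z <- p$charge[multi]
        p$mz[multi] <- p$mz[multi] * z - (z - 1) * .protonMass
        p$charge[multi] <- 1L
    }
    o <- order(p$mz)
    p <- p[o, , drop = FALSE]
    ## group peaks chained within the merge window
    gaps <- diff(p$mz)
    group <- cumsum(c(1, as.numeric(gaps > mergeTolerance)))
    if (max(group) < nrow(p)) {
        mzs <- vapply(split(seq_len(nrow(p)), group), function(i) {
            stats::weighted.mean(p$mz[i], p$intensity[i] + 1e-12)
        }, numeric(1L))
        ints <- vapply(split(p$intensity, group), sum, numeric(1L))
        zs <- vapply(split(p$charge, group), function(g) {
            if (all(is.na(g))) NA_integer_ else 1L
        }, integer(1L))
        p <- data.frame(mz = mzs, intensity = ints, charge = zs)
    }
    .withPeaks(spectrum, p)
}
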