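#' Default decomposer configuration
#'
#' All tunable parameters of the pipeline, with the standard defaults:
#' \describe{
#'   \item{minPeakIntensity}{global intensity prefilter, 15 counts
#'     (inclusive).}
#'   \item{oxoniumTolerance}{m/z window for oxonium ion detection and
#'     removal, 0.02 Da.}
#'   \item{minOxoniumIons}{minimum number of distinct oxonium ions, 1.}
#'   \item{oxoniumSumThreshold}{minimum summed relative oxonium intensity,
#'     0.0047 (fraction of total spectrum intensity).}
#'   \item{patternOffsets}{the eight core-pattern offsets, Da (see
#'     [patternTemplate()]).}
#'   \item{minReferenceMz}{minimum m/z of a candidate reference (Y1) peak,
#'     850 Da.}
#'   \item{minReferenceRelIntensity}{minimum reference intensity as a
#'     fraction of the base peak, 0.1.}
#'   \item{patternTolerance}{m/z window for pattern peak matching, 0.05
#'     Da.}
#'   \item{minPatternPeaks}{minimum matched pattern peaks (reference
#'     included), 2.}
#'   \item{compositionTolerance}{mass window for glycan composition
#'     matching, 0.1 Da.}
#'   \item{monosaccharides}{residue mass/bounds table
#'     ([monosaccharideTable()]).}
#'   \item{oxoniumIons}{the six-ion table ([oxoniumTable()]).}
#'   \item{isotopeSpacing}{13C-12C spacing for isotope grouping and
#'     identification comparison, 1.00335 Da.}
#'   \item{isotopeMaxK}{maximum isotope offset considered, 3.}
#'   \item{mergeTolerance}{m/z window for merging peaks after charge
#'     deconvolution, 0.001 Da.}
#' }
#'
#' @return Named list of parameters.
#' @examples
#' cfg <- defaultConfig()
#' cfg$oxoniumSumThreshold
#' @export
defaultConfig <- function() {
    list(
        minPeakIntensity = 15,
        oxoniumTolerance = 0.02,
        minOxoniumIons = 1L,
        oxoniumSumThreshold = 0.0047,
        patternOffsets = patternTemplate(),
        minReferenceMz = 850,
        minReferenceRelIntensity = 0.1,
        patternTolerance = 0.05,
        minPatternPeaks = 2L,
        compositionTolerance = 0.1,
        monosaccharides = monosaccharideTable(),
        oxoniumIons = oxoniumTable(),
        isotopeSpacing = 1.00335,
        isotopeMaxK = 3L,
        mergeTolerance = 0.001
    )
}

.scalarConfigKeys <- c(
    min_peak_intensity = "minPeakIntensity",
    oxonium_tolerance = "oxoniumTolerance",
    min_oxonium_ions = "minOxoniumIons",
    oxonium_sum_threshold = "oxoniumSumThreshold",
    min_reference_mz = "minReferenceMz",
    min_reference_rel_intensity = "minReferenceRelIntensity",
    pattern_tolerance = "patternTolerance",
    min_pattern_peaks = "minPatternPeaks",
    composition_tolerance = "compositionTolerance",
    isotope_spacing = "isotopeSpacing",
    isotope_max_k = "isotopeMaxK",
    merge_tolerance = "mergeTolerance"
)

.checkConfig <- function(config) {
    tol <- c("oxoniumTolerance", "patternTolerance", "compositionTolerance",
             "mergeTolerance", "isotopeSpacing")
    for (k in tol)
        if (!is.numeric(config[[k]]) || config[[k]] <= 0)
            stop("config parameter '", k, "' must be > 0")
    if (config$minPeakIntensity < 0)
        stop("minPeakIntensity must be >= 0")
    offs <- config$patternOffsets
    if (!is.numeric(offs) || is.unsorted(offs, strictly = TRUE) ||
        !any(offs == 0))
        stop("patternOffsets must be strictly increasing and contain 0")
    .checkMonosaccharideTable(config$monosaccharides)
    invisible(config)
}

#' Read a flat key=value configuration file
#'
#' Parses a human-readable configuration file with one `key = value` pair
#' per line (`#` starts a comment). Unset keys keep their defaults, so an
#' empty file reproduces [defaultConfig()] exactly. Recognised keys are the
#' snake_case names of the scalar parameters (e.g. `min_peak_intensity`,
#' `oxonium_sum_threshold`), `pattern_offsets` (comma-separated),
#' `oxonium_<name>` for oxonium table m/z values, and
#' `<monosaccharide>_mass`, `<monosaccharide>_min`, `<monosaccharide>_max`
#' for the composition table.
#'
#' @param path Path to the configuration file, or `NULL` for defaults.
#' @param base Configuration to override; defaults to [defaultConfig()].
#' @return Named list of parameters (see [defaultConfig()]).
#' @export
readConfig <- function(path = NULL, base = defaultConfig()) {
    config <- base
    if (is.null(path))
        return(.checkConfig(config))
    if (!file.exists(path))
        stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (line in lines) {
        if (!grepl("=", line, fixed = TRUE))
            stop("malformed config line (expected key = value): ", line)
        key <- trimws(sub("=.*$", "", line))
        value <- trimws(sub("^[^=]*=", "", line))
        config <- .applyConfigEntry(config, key, value)
    }
    .checkConfig(config)
}

.applyConfigEntry <- function(config, key, value) {
    num <- function(v) {
        x <- suppressWarnings(as.numeric(v))
        if (anyNA(x)) stop("non-numeric config value for '", key, "': ", v)
        x
    }
    if (key %in% names(.scalarConfigKeys)) {
        target <- .scalarConfigKeys[[key]]
        x <- num(value)
        if (target %in% c("minOxoniumIons", "minPatternPeaks", "isotopeMaxK"))
            x <- as.integer(x)
        config[[target]] <- x
        return(config)
    }
    if (key == "pattern_offsets") {
        config$patternOffsets <- sort(num(strsplit(value, ",")[[1L]]))
        return(config)
    }
    if (startsWith(key, "oxonium_")) {
        name <- sub("^oxonium_", "", key)
        tab <- config$oxoniumIons
        if (!name %in% tab$name)
            stop("unknown oxonium ion in config: ", name)
        tab$mz[tab$name == name] <- num(value)
        config$oxoniumIons <- tab
        return(config)
    }
    m <- regmatches(key, regexec("^([A-Za-z]+)_(mass|min|max)$", key))[[1L]]
    if (length(m) == 3L && m[2L] %in% config$monosaccharides$name) {
        tab <- config$monosaccharides
        i <- match(m[2L], tab$name)
        tab[[m[3L]]][i] <- if (m[3L] == "mass") num(value)
                           else as.integer(num(value))
        config$monosaccharides <- tab
        return(config)
    }
    stop("unknown config key: ", key)
}

#' Write a configuration as a flat key=value file
#'
#' Inverse of [readConfig()]: the written file, read back, reproduces the
#' configuration.
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
    .checkConfig(config)
    fmt <- function(x) format(x, digits = 15, scientific = FALSE,
                              trim = TRUE)
    lines <- character(0)
    for (key in names(.scalarConfigKeys)) {
        lines <- c(lines,
                   paste(key, "=", fmt(config[[.scalarConfigKeys[[key]]]])))
    }
    lines <- c(lines, paste("pattern_offsets =",
                            paste(fmt(config$patternOffsets),
                                  collapse = ",")))
    tab <- config$oxoniumIons
    lines <- c(lines, paste0("oxonium_", tab$name, " = ", fmt(tab$mz)))
    ms <- config$monosaccharides
    for (i in seq_len(nrow(ms))) {
        lines <- c(lines,
                   paste0(ms$name[i], "_mass = ", fmt(ms$mass[i])),
                   paste0(ms$name[i], "_min = ", ms$min[i]),
                   paste0(ms$name[i], "_max = ", ms$max[i]))
    }
    writeLines(lines, path)
    invisible(path)
}
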