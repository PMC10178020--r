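#' @import methods
NULL

#' Spectrum: a centroided MS/MS peak list
#'
#' The universal unit of work: a precursor descriptor plus an ordered peak
#' list. Peaks are stored as a data.frame with columns `mz` (Da, ascending),
#' `intensity` (counts, >= 0) and `charge` (positive integer, `NA` when
#' unknown). Inputs are assumed centroided and deisotoped; per-peak charge
#' annotations, where present, drive [chargeDeconvolute()].
#'
#' @slot id Opaque spectrum identifier.
#' @slot precursorMz Precursor m/z in Da.
#' @slot precursorCharge Precursor charge (positive integer; `NA` when the
#'   source file does not state it).
#' @slot peaks data.frame of peaks, sorted ascending by `mz`.
#' @slot metadata Open key-value list (e.g. `glycanMoietyMass` on glycan
#'   moiety composite spectra).
#'
#' @aliases Spectrum-class
#' @exportClass Spectrum
setClass("Spectrum",
    representation(
        id = "character",
        precursorMz = "numeric",
        precursorCharge = "integer",
        peaks = "data.frame",
        metadata = "list"
    )
)

setValidity("Spectrum", function(object) {
    msg <- character(0)
    p <- object@peaks
    if (!all(c("mz", "intensity", "charge") %in% names(p)))
        msg <- c(msg, "peaks must have columns mz, intensity, charge")
    else {
        if (any(p$mz <= 0)) msg <- c(msg, "peak m/z must be positive")
        if (any(p$intensity < 0))
            msg <- c(msg, "peak intensity must be non-negative")
        if (is.unsorted(p$mz)) msg <- c(msg, "peaks must be sorted by m/z")
        if (any(!is.na(p$charge) & p$charge < 1L))
            msg <- c(msg, "peak charge must be positive or NA")
    }
    if (length(object@id) != 1L) msg <- c(msg, "id must be length 1")
    if (length(object@precursorMz) != 1L || is.na(object@precursorMz) ||
        object@precursorMz <= 0)
        msg <- c(msg, "precursorMz must be a single positive number")
    if (length(object@precursorCharge) != 1L ||
        (!is.na(object@precursorCharge) && object@precursorCharge < 1L))
        msg <- c(msg, "precursorCharge must be >= 1 or NA")
    if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param id Spectrum identifier.
#' @param precursorMz Precursor m/z (Da).
#' @param precursorCharge Precursor charge; `NA` if unknown.
#' @param mz,intensity Numeric vectors of equal length.
#' @param charge Optional integer vector of per-peak charges (`NA` =
#'   unknown).
#' @param metadata Named list of additional metadata.
#' @return A [Spectrum-class] object with peaks sorted ascending by m/z.
#' @examples
#' s <- Spectrum("scan1", 1000.5, 2L, mz = c(204.09, 366.14, 900.4),
#'               intensity = c(50, 80, 500))
#' s
#' @export
Spectrum <- function(id, precursorMz, precursorCharge = NA_integer_,
                     mz = numeric(0), intensity = numeric(0),
                     charge = NA_integer_, metadata = list()) {
    n <- length(mz)
    stopifnot(length(intensity) == n)
    charge <- suppressWarnings(as.integer(charge))
    if (length(charge) == 1L) charge <- rep(charge, n)
    stopifnot(length(charge) == n)
    o <- order(mz)
    peaks <- data.frame(mz = as.numeric(mz)[o],
                        intensity = as.numeric(intensity)[o],
                        charge = charge[o])
    new("Spectrum", id = as.character(id),
        precursorMz = as.numeric(precursorMz),
        precursorCharge = suppressWarnings(as.integer(precursorCharge)),
        peaks = peaks, metadata = metadata)
}

#' @describeIn Spectrum Peak table accessor (data.frame with `mz`,
#'   `intensity`, `charge`).
#' @param object,x A `Spectrum`.
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname Spectrum
#' @export
setMethod("peaks", "Spectrum", function(x) x@peaks)

#' @rdname Spectrum
#' @export
setGeneric("peakCount", function(x) standardGeneric("peakCount"))

#' @rdname Spectrum
#' @export
setMethod("peakCount", "Spectrum", function(x) nrow(x@peaks))

#' @rdname Spectrum
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))

#' @rdname Spectrum
#' @export
setMethod("precursorMz", "Spectrum", function(x) x@precursorMz)

#' @rdname Spectrum
#' @export
setGeneric("precursorCharge", function(x) standardGeneric("precursorCharge"))

#' @rdname Spectrum
#' @export
setMethod("precursorCharge", "Spectrum", function(x) x@precursorCharge)

#' @rdname Spectrum
#' @export
setGeneric("spectrumId", function(x) standardGeneric("spectrumId"))

#' @rdname Spectrum
#' @export
setMethod("spectrumId", "Spectrum", function(x) x@id)

#' @rdname Spectrum
#' @export
setGeneric("spectrumMetadata", function(x) standardGeneric("spectrumMetadata"))

#' @rdname Spectrum
#' @export
setMethod("spectrumMetadata", "Spectrum", function(x) x@metadata)

#' @rdname Spectrum
#' @param value Replacement metadata list.
#' @export
setGeneric("spectrumMetadata<-",
           function(x, value) standardGeneric("spectrumMetadata<-"))

#' @rdname Spectrum
#' @export
setReplaceMethod("spectrumMetadata", "Spectrum", function(x, value) {
    x@metadata <- value
    validObject(x)
    x
})

setMethod("show", "Spectrum", function(object) {
    z <- object@precursorCharge
    cat("Spectrum '", object@id, "': precursor m/z ",
        format(object@precursorMz, digits = 9), " (",
        if (is.na(z)) "charge unknown" else paste0(z, "+"), "), ",
        nrow(object@peaks), " peaks\n", sep = "")
    if (length(object@metadata))
        cat("  metadata: ",
            paste(names(object@metadata), collapse = ", "), "\n", sep = "")
})

## internal: rebuild a spectrum with a replaced peak table (kept sorted)
.withPeaks <- function(spectrum, peaks) {
    o <- order(peaks$mz)
    spectrum@peaks <- peaks[o, , drop = FALSE]
    rownames(spectrum@peaks) <- NULL
    validObject(spectrum)
    spectrum
}
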