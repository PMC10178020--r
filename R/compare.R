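#' Identification-equivalence rule for glycopeptide identifications
#'
#' Two identifications count as the same when the peptide moiety sequences
#' are identical and the glycan moiety masses agree within `massTol` after
#' allowing up to `maxIsotopes` 13C isotope offsets in either direction
#' (either tool may have picked a non-monoisotopic precursor):
#' `min_k | |dM| - k * 1.00335 | <= massTol` for `k = 0..maxIsotopes`.
#'
#' @param a,b Identifications: lists or one-row data.frames with at least
#'   `peptide` and `glycan_mass` fields.
#' @param massTol Mass tolerance in Da (default 0.05).
#' @param maxIsotopes Maximum isotope offset (default 3).
#' @param spacing Isotope spacing in Da (default 1.00335).
#' @return Logical. Symmetric in `a` and `b`.
#' @examples
#' a <- list(peptide = "EEQYNSTYR", glycan_mass = 1444.5339)
#' b <- list(peptide = "EEQYNSTYR", glycan_mass = 1445.5372)
#' sameIdentification(a, b)  # one isotope apart
#' @export
sameIdentification <- function(a, b, massTol = 0.05, maxIsotopes = 3L,
                               spacing = 1.00335) {
    stopifnot(massTol > 0, maxIsotopes >= 0)
    if (!identical(as.character(a$peptide), as.character(b$peptide)))
        return(FALSE)
    d <- abs(as.numeric(a$glycan_mass) - as.numeric(b$glycan_mass))
    any(abs(d - (0:maxIsotopes) * spacing) <= massTol)
}

.dedupeIdentifications <- function(x, label) {
    stopifnot(is.data.frame(x),
              all(c("source_id", "peptide", "glycan_mass") %in% names(x)))
    if (!anyDuplicated(x$source_id))
        return(x)
    message("duplicate source_id in ", label,
            ": keeping best-scoring record per spectrum")
    score <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
    score[is.na(score)] <- -Inf
    keep <- unlist(lapply(split(seq_len(nrow(x)), x$source_id),
                          function(i) i[which.max(score[i])]))
    x[sort(keep), , drop = FALSE]
}

#' Agreement between two identification result sets
#'
#' Identifications are keyed by spectrum (`source_id`). Spectra identified
#' in both sets are split by [sameIdentification()]; the four counts
#' partition the union of spectrum ids. Duplicate ids within one set are
#' reduced to the best-scoring record.
#'
#' @param setA,setB data.frames with columns `source_id`, `peptide`,
#'   `glycan_mass` and optionally `score`.
#' @inheritParams sameIdentification
#' @return Named integer vector: `bothSame`, `bothDifferent`, `aOnly`,
#'   `bOnly`.
#' @export
agreementTable <- function(setA, setB, massTol = 0.05, maxIsotopes = 3L,
                           spacing = 1.00335) {
    setA <- .dedupeIdentifications(setA, "setA")
    setB <- .dedupeIdentifications(setB, "setB")
    shared <- intersect(setA$source_id, setB$source_id)
    same <- vapply(shared, function(id) {
        sameIdentification(setA[setA$source_id == id, ],
                           setB[setB$source_id == id, ],
                           massTol, maxIsotopes, spacing)
    }, logical(1L))
    c(bothSame = sum(same), bothDifferent = sum(!same),
      aOnly = length(setdiff(setA$source_id, setB$source_id)),
      bOnly = length(setdiff(setB$source_id, setA$source_id)))
}

#' Read / write delimited identification tables
#'
#' Tab-separated tables with columns `source_id`, `peptide`,
#' `glycan_mass`, and optionally `charge` and `score`.
#'
#' @param path File path.
#' @return [readIdentifications()]: a data.frame.
#' @export
readIdentifications <- function(path) {
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("source_id", "peptide", "glycan_mass")
    if (!all(need %in% names(x)))
        stop("identification table must have columns: ",
             paste(need, collapse = ", "))
    x
}

#' @rdname readIdentifications
#' @param x Identification data.frame.
#' @export
writeIdentifications <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
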