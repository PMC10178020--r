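Package: GlycoDecomposer
Title: Decomposition of N-Glycopeptide Fragmentation Spectra into
    Peptide and Glycan Moiety Spectra
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies centroided tandem mass spectra as glycopeptide or
    non-glycopeptide spectra using diagnostic oxonium ions, locates the
    conserved N-glycan core Y-ion fragmentation pattern to infer the mass
    of the peptide moiety, and decomposes each hybrid glycopeptide
    spectrum into a peptide-moiety composite spectrum (suitable for
    conventional peptide database search) and a glycan-moiety record.
    Glycan compositions consistent with the inferred glycan mass are
    enumerated exhaustively under per-monosaccharide count bounds,
    independent of any glycan database. Includes MGF and ms2 peak-list
    readers and writers, charge deconvolution, a ground-truth simulator
    for glycopeptide and non-glycopeptide spectra, and an
    identification-equivalence rule for comparing result sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
biocViews: Proteomics, MassSpectrometry, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
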