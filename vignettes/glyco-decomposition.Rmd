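---
title: "Decomposing N-glycopeptide fragmentation spectra"
author: "GlycoDecomposer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing N-glycopeptide fragmentation spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GlycoDecomposer)
```

## The problem

Collision-induced dissociation (CID) spectra of N-glycopeptides are
hybrids: they mix peptide backbone fragments (b/y ions, with and without
the proximal HexNAc), glycosidic-bond fragments that retain the peptide
(Y ions), and low-mass glycan oxonium ions. Searching such a spectrum
directly with a peptide search engine fails, because most of its signal
is glycan-derived, and glycan databases cannot cover the compositional
diversity of real samples — particularly disease-specific glycoforms.

GlycoDecomposer separates the two halves of the problem. Each spectrum is
processed in three steps:

1. **Oxonium filter.** Diagnostic oxonium ions decide whether a spectrum
   is a glycopeptide spectrum at all. Non-glycopeptide spectra pass
   through untouched, ready for a conventional peptide search.
2. **Core pattern finder.** All N-glycans share the
   Asn–HexNAc–HexNAc–Hex–Hex–Hex core, whose stepwise CID cleavage
   produces a Y-ion ladder with fixed mass spacings. Locating that
   pattern pins down the mass of the peptide moiety.
3. **Spectrum decomposer.** The spectrum is split into a peptide-moiety
   composite spectrum (pseudo-precursor `[peptide + HexNAc]`^1+^, glycan
   peaks removed) and a glycan-moiety record carrying the inferred glycan
   mass, from which matching monosaccharide compositions are enumerated
   without any glycan database.

## The model and its assumptions

Inputs are centroided, deisotoped peak lists (MGF or ms2) with known
precursor m/z and charge. All m/z values follow positive-mode, singly
protonated conventions; the proton mass is 1.00727646 Da throughout.

**Step 1 — oxonium classification.** Six ions are used: HexNAc-Hex
(366.139472), HexNAc-Hex-NeuAc (657.234889), HexNAc-Hex-dHex
(512.19793), NeuAc (292.102693), NeuAc−H~2~O (274.092128) and HexNAc
(204.0867). For each table entry the most intense peak within ±0.02 Da
is its match (one peak per entry, one entry per peak; a contested peak
goes to the closer entry). The classifier requires at least 1 distinct
ion and a summed matched intensity of at least 0.0047 of the total
spectrum intensity, both bounds inclusive. Because the statistic is a
ratio over the same spectrum, it is invariant under uniform intensity
scaling; adding non-oxonium signal can only lower it.

**Step 2 — core pattern.** The template holds eight signed offsets
relative to the Y~1~ reference peak:
`(-220.0821, -203.0794, -120.0423, 0, 203.0794, 365.1322, 527.185,
689.2378)`. The −203.0794 entry is the bare peptide Y~0~; −120.0423 is a
cross-ring fragment of the proximal HexNAc; −220.0821 is a reported
satellite of Y~0~ associated with loss at the glycosylated asparagine
(kept verbatim even though it matches no textbook deamidation shift);
the positive offsets climb the core, one HexNAc then three Hex.
Candidate references must have m/z ≥ 850 Da (below the lightest
plausible tryptic glycopeptide Y~1~ region) and intensity ≥ 10% of the
base peak, since the Y~1~ ion is typically among the strongest peaks.
An offset matches when a peak lies within ±0.05 Da of the predicted
position; placements with at least 2 matched peaks (reference included)
and a positive implied glycan mass are kept. Matches are ranked by
number of matched peaks, then reference intensity, then (as a
deterministic tie-break this package adds) ascending reference m/z.
Partial matches are deliberately allowed: they keep the method
applicable to truncated or disease-specific cores at the price of
occasional wrong placements, which the ranking mitigates.

**Step 3 — decomposition.** The peptide composite is built by charge
deconvolution (annotated z > 1 peaks mapped to `mz·z − (z−1)·proton`,
duplicates within 0.001 Da merged by intensity-weighted mean), removal
of peaks within ±0.02 Da of any table oxonium ion, and truncation of
everything above `referenceMz + 0.05` — so the Y~1~ peak itself
survives, and `peptideMoietyMass + glycanMoietyMass` equals the
precursor neutral mass exactly by construction. The glycan composite is
the deconvoluted parent with the glycan mass as metadata.

**Composition generation.** Every count vector of Hex (162.05282, 0–12),
HexNAc (203.07937, 1–7), dHex (146.05791, 0–3) and NeuAc (291.09542,
0–4) whose mass lies within ±0.1 Da of the query is returned. The
implementation is a depth-first walk with residual-mass pruning, but its
contract is set-equality with a plain four-nested-loop enumeration —
completeness, not speed, is the point, and the test suite enforces it
against an independent brute-force oracle.

## Two mass scales

Constants printed in the configuration (monosaccharide residues, oxonium
m/z, pattern offsets) are stored and used verbatim, so a run of this
package is auditable against its configuration file key by key.
Independently, `oxoniumMz()` recomputes oxonium m/z from monoisotopic
element masses (C 12, H 1.00782503, N 14.0030740, O 15.9949146, proton
1.00727646); this reproduces the table to 6 decimals for four of the six
ions, to 4 for HexNAc (tabulated at 4), while the HexNAc-Hex-dHex entry
sits ~0.55 mDa above its theoretical value and is kept as configured.
Amino-acid masses are the standard monoisotopic residue table.

## What the simulator emulates — and what it does not

`simulateGlycopeptide()` emits the peak classes the decomposer relies
on: oxonium ions implied by the composition (HexNAc always, Hex- and
NeuAc-derived ions only when those residues are present), the eight-peak
core pattern at its true positions, b/y and b/y+HexNAc ions (the
+HexNAc series only for fragments spanning the glycosylation site,
placed at the first N-X(≠P)-S/T sequon), and uniform random noise.
Fragment intensities are log-uniform with the Y~1~ biased to be among
the most intense, matching its behaviour in real CID spectra. Defaults —
ladder completeness 0.9, b/y coverage 0.7, oxonium intensity fraction
0.05, 30 noise peaks over (200, precursor m/z × z) — were chosen once as
a plausible mid-quality glycopeptide spectrum: most core peaks present,
partial backbone coverage, oxonium signal an order of magnitude above
the 0.0047 decision threshold, and noise dense enough to create decoy
reference peaks.

`simulateNonglyco()` produces b/y-plus-noise negatives and displaces any
peak that would fall inside an oxonium window, so the negative class is
clean by construction; false-positive rates measured on it reflect the
filter logic, not pool luck.

The simulator does **not** model isotope envelopes (inputs are
deisotoped by contract), collision-energy-dependent fragmentation
efficiency, co-isolated precursors, or correlated chemical noise. Clean
recovery rates on simulated cohorts therefore demonstrate correctness of
the decomposition logic, not expected performance on instrument data:
on real plasma data this class of method places the correct pattern at
rank 1 in roughly three quarters of identified spectra. The package's
own bars on 1,000 simulated noisy spectra — rank-1 recovery ≥ 90%,
correct pattern at any rank ≥ 98% — are artifact-level regression bars,
and the suite measures 100% at the default noise level.

## Numerical choices and degenerate inputs

* All thresholds are inclusive (the configuration states magnitudes, not
  boundary semantics; inclusive is the only choice that makes the
  printed values themselves pass).
* The prefilter (intensity ≥ 15) runs before everything; its unit is
  whatever the input file's intensity column uses.
* Unknown per-peak charge is treated as 1+ during deconvolution;
  annotations are advisory because inputs are nominally decharged.
* Empty spectra, empty candidate lists and empty match lists flow
  through as empty results, never errors; per-spectrum failures inside
  `decomposeStream()` are logged and skipped so one malformed record
  cannot abort a run.
* Pattern placements implying a non-positive glycan mass are discarded —
  the precursor must outweigh its peptide moiety.
* Isotope grouping of pattern matches uses 1.00335 Da spacing, k ≤ 3,
  tolerance 0.05 Da; it informs reporting, never ranking. The same
  spacing drives the identification-equivalence rule
  (`sameIdentification()`: identical peptide and glycan masses within
  0.05 Da after at most 3 isotope offsets in either direction — applied
  symmetrically, since either result set may have picked a
  non-monoisotopic precursor).

## Worked example

```{r example}
sim <- simulateGlycopeptide("EEQYNSTYR", c(Hex = 5, HexNAc = 4, NeuAc = 2),
                            charge = 2L, params = simParams(seed = 1))
res <- decomposeSpectrum(sim$spectrum)
res$outcome
patternMatch(res$pair)
compositionsForPair(res$pair)$compositions
```

The inferred peptide moiety mass can be compared with the truth:

```{r truth}
peptideMoietyMass(patternMatch(res$pair)) - peptideNeutralMass("EEQYNSTYR")
```

## Problem sizes used by the checks

The regression suite and the `scripts/acceptance.R` summary use 200
random query masses for the composition-generator oracle, 100 simulated
spectra for conservation checks, and 1,000 spectra per condition
(noisy glycopeptide recovery; clean negatives; clean positives) — large
enough for stable rates while keeping a full run in the order of half a
minute on one core.

## Known limitations

* O-glycopeptides have no conserved core ladder; the pattern finder is
  N-glycan-specific.
* The composition generator uses the glycan mass alone; glycan fragment
  ions are not yet used to constrain compositions, and no topology is
  inferred.
* No FDR model is attached to either moiety; downstream identification
  tools own that.
* MGF and ms2 are the only dialects read or written; profile-mode or
  vendor-format data must be converted upstream.
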