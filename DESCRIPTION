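Package: idrscape
Title: Physicochemical Characterization of Intrinsically Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-level characterization of intrinsically disordered
    protein regions (IDRs): Henderson-Hasselbalch net charge and theoretical
    isoelectric point with proteome acidity percentiles, charge-hydropathy
    (Uversky-plane) classification with windowed Kyte-Doolittle hydropathy,
    amino-acid composition enrichment with bootstrap error estimates,
    SUMO-interacting-motif and tandem-repeat scanning, exponential smoothing
    of per-residue disorder score tracks, rule-based ortholog triage from
    profile-HMM domain hit tables, and average-linkage clustering of
    negative-log-probability dissimilarity matrices with Newick export.
    Includes seeded synthetic-data generators for every input class so the
    full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
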