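Package: adamsh3
Title: SH3 Interaction Profiling of ADAM Metalloprotease Cytosolic Tails
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for profiling SH3 domain interactions of
    ADAM metalloprotease cytosolic tails. Scans tail sequences for canonical
    and atypical SH3 target motifs, merges hits into proline clusters and
    tiles them into array peptides; quantifies phage-display biopanning
    screens (enrichment, dominance fractions, tiered partner classification)
    and designs reduction libraries for sequential screening; implements the
    CelluSpot peptide-array quantification chain (triplicate averaging,
    empty-spot background model, per-probe normalization, hierarchical
    clustering and TreeView-compatible heat-map export); and provides a
    seeded synthetic-data generator emulating affinity-weighted biopanning
    and peptide-array slides so every stage is testable by parameter
    recovery without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
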