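Package: fishdesign
Title: Species-Specific 16S rRNA FISH Probe Design with Thermodynamic and
    Secondary-Structure Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design species-specific oligonucleotide probes for fluorescence
    in situ hybridization (FISH) against 16S rRNA targets. Candidate antisense
    oligos are enumerated from a target species' 16S gene, filtered on base
    composition, screened for specificity against a non-target reference
    database by exhaustive mismatch counting, annotated with nearest-neighbor
    duplex thermodynamics (melting temperature under hybridization-buffer salt
    and formamide conditions), and filtered on the minimum free energy of
    probe self-structure so that candidates forming stable hairpins are
    avoided. Includes a seeded synthetic 16S community generator with
    conserved blocks and planted species-specific regions, in-silico staining
    predictions reproducing universal-probe/nonsense-probe control logic, and
    quality-control filters for amplicon tags and metagenomic reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
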