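Package: repfish
Title: Repeat-Targeted Oligonucleotide FISH Probe Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Design of oligonucleotide probes for fluorescence in situ
    hybridization (FISH) against highly repetitive DNA such as satellite
    arrays. Discovers repetitive genomic intervals de novo by k-mer counting
    with a sliding-window rule, mines thermodynamically valid candidate
    oligos (length, melting temperature and GC constraints under
    nearest-neighbor thermodynamics with salt and formamide corrections),
    ranks candidates by target-specific k-mer enrichment, and selects final
    probes by in-silico specificity profiling: seed-and-extend local
    alignment of each candidate against the whole assembly, a two-state
    duplex-formation probability for every alignment site under FISH
    hybridization conditions, on/off-target binding sums and binned
    off-target culling. Includes a deterministic synthetic-genome generator
    with planted tandem arrays for testing, three pipeline execution modes,
    and tabular/bedGraph reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
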