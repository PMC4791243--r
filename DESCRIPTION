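Package: gbmcharter
Title: Variant, RNA-Editing and Gene-Fusion Characterization of Glioblastoma Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment characterization of tumour cell-line sequencing
    calls: variant spectrum statistics (Ti/Tv, zygosity, functional classes,
    indel size spectrum), a cancer-specific SNV filter cascade driven by
    population and cancer databases, an RNA-editing detection cascade with
    Alu/non-Alu handling and artifact filters, multi-caller gene-fusion
    consensus with in-frame fusion ORF assembly, and differential-expression
    direction concordance. Ships a deterministic synthetic-fixture generator
    with machine-readable planted truth so the whole pipeline is exercisable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
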