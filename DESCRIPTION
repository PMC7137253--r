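Package: sisprofiler
Title: Genome-Wide Characterization of Stable Intronic Sequence RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies RNA-seq peaks into stable intronic sequence RNAs
    (sisRNAs) against a reference gene set, and characterizes the resulting
    sisRNA population: per-gene and per-intron distribution summaries,
    sequence composition statistics (GC content, CpG and CA|TG density,
    reverse-complement-collapsed k-mer observed/expected ratios), binned
    sisRNA density profiles along concatenated intron transcripts,
    position-weight-matrix motif enrichment against a whole-genome scan,
    and anchored per-base conservation metaprofiles. Includes a seeded
    synthetic-genome generator that plants sisRNAs with known composition,
    positional, motif and expression-coupling structure so every pipeline
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
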