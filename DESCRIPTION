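Package: utrshiftr
Title: Isoform Usage and 3'UTR Length-Shift Analysis for NMD Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Isoform-level transcriptome analysis for studies of
    nonsense-mediated mRNA decay (NMD) and 3'UTR length control. Annotates
    assembled transcript models with open reading frames taken from the most
    upstream compatible reference CDS, classifies premature termination
    codons under the 50-nt rule, quantile-normalizes isoform expression,
    computes isoform fractions and "primarily expressed" classes, partitions
    genes into four isoform-usage subsets by differential isoform fraction,
    and summarizes shifts in expression-weighted 3'UTR length between
    conditions. Includes a synthetic-data generator that emits genome FASTA,
    reference and assembled GTF, expression tables and a ground-truth table
    with planted NMD-loss signatures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
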