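#!/usr/bin/env Rscript

# Step 2 — ORF/PTC annotation of the assembled transcripts.
#
# Reads the scenario written by 01_simulate.R, anchors each assembled
# transcript to the most upstream compatible reference CDS start, scans
# the downstream reading frame, and classifies PTC status under the 50-nt
# rule. Writes results/annotation.tsv and reports recovery against the
# generator's ground truth.

suppressPackageStartupMessages(library(utrshiftr))

models <- read_gtf("results/scenario/assembled.gtf", "transcripts")
refs <- read_gtf("results/scenario/reference.gtf", "reference_cds")
genome <- read_genome_fasta("results/scenario/genome.fa")

ann <- annotate_transcripts(models, refs, genome)
write_annotation(ann, "results/annotation.tsv")

cat(sprintf("annotated %d transcripts\n", nrow(ann)))
print(table(ann$orf_class))

truth <- read_truth("results/scenario/truth.tsv")
tr <- truth[match(ann$transcript_id, truth$transcript_id), ]
cat(sprintf("UTR/ORF length mismatches vs truth: %d\n",
            sum(ann$utr5_len != tr$utr5_len | ann$orf_len != tr$orf_len |
                  ann$utr3_len != tr$utr3_len)))
cat(sprintf("PTC class mismatches vs truth: %d\n",
            sum((ann$orf_class == "PTC_POSITIVE") != tr$ptc)))
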