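#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream analyses:
# a count matrix with a planted TF and target genes, a peak genome with
# constrained co-binding of two factors, nucleosome occupancy with planted
# nucleosomal peaks, gene models near the peaks, and a proteomics LFQ table
# with planted enrichment. All planted truth is written alongside.

suppressPackageStartupMessages(library(stomatalchrom))

seed <- 1
outdir <- "results/data"
cfg <- demo_dataset(outdir, seed = seed)

cat("Synthetic study data written to", outdir, "\n")
cat("  counts:", length(readLines(file.path(outdir, "counts.cells.txt"))),
    "cells x", length(readLines(file.path(outdir, "counts.genes.txt"))),
    "genes; planted targets:",
    length(readLines(file.path(outdir, "truth_target_genes.txt"))), "\n")
cat("  peaks:", nrow(read_bed(file.path(outdir, "peaks_a.narrowPeak"))),
    "contigs with G-box + partner sites at constrained 8 bp spacing\n")
cat("  nucleosomal truth:",
    length(readLines(file.path(outdir, "truth_nucleosomal_peaks.txt"))),
    "of the peaks carry a 147 bp occupancy plateau\n")
cat("  LFQ: 300 proteins x 9 samples;",
    length(readLines(file.path(outdir, "truth_enriched_proteins.txt"))),
    "planted bait-enriched proteins\n")
cat("  pipeline config:", cfg, "\n")
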