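#!/usr/bin/env Rscript
# Nucleosome occupancy at binding sites and motif-presence stringency:
# classify peaks as nucleosomal vs non-nucleosomal from the occupancy track,
# score accuracy against the planted truth, and compare the fraction of
# peaks harbouring the G-box motif between the two classes.

suppressPackageStartupMessages(library(stomatalchrom))

data_dir <- "results/data"
peaks <- read_bed(file.path(data_dir, "peaks_a.narrowPeak"))
track <- read_track(file.path(data_dir, "occupancy.bedGraph"))
truth <- readLines(file.path(data_dir, "truth_nucleosomal_peaks.txt"))

nc <- classify_nucleosomal(peaks, track)  # threshold: track mean + 1 SD
acc <- mean((nc$label == "nucleosomal") == (nc$peak_id %in% truth))
cat(sprintf("nucleosomal classification: %d/%d peaks nucleosomal, accuracy %.3f\n",
            sum(nc$label == "nucleosomal"), nrow(nc), acc))
write.table(format(nc, digits = 10), "results/nucleosome_classes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

genome <- read_genome(file.path(data_dir, "genome.fa"))
pwm <- read_pwm(file.path(data_dir, "pwm_a.pfm"))
subsets <- split(peaks, ifelse(nc$label[match(peaks$name, nc$peak_id)] ==
                                 "nucleosomal", "nucleosomal", "non_nucleosomal"))
pres <- motif_presence(subsets, pwm, genome, window = 50)
cat("\nmotif presence within 50 bp of summits, by nucleosome class:\n")
print(pres, digits = 4)
write.table(format(pres, digits = 10), "results/motif_presence.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# metaprofile of occupancy over the peaks (summit-centred anchors)
anchors <- data.frame(chrom = peaks$chrom,
                      start = pmax(0, peak_center(peaks) - 60),
                      end = peak_center(peaks) + 60)
mp <- metaprofile(track, NULL, anchors, flank = 50, n_bins = 12)
write.table(format(mp, digits = 10), "results/occupancy_metaprofile.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("\nmetaprofile: central-body mean %.2f vs flank mean %.2f\n",
            mean(mp$value[mp$region == "body"]),
            mean(mp$value[mp$region != "body"])))
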