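#!/usr/bin/env Rscript
# Cross-method support: how much of the DCMS region set is independently
# recovered by the FLK scan, and how both relate to the truth windows.
# Writes results/overlap_summary.tsv.

suppressMessages(library(sweepscan))
dcms_files <- list.files("results/dcms", "^dcms_regions_.*\\.tsv$",
                         full.names = TRUE)
dcms <- do.call(rbind, lapply(dcms_files, read_regions))
flk <- read_regions("results/flk/flk_regions_all.tsv")
truth <- jsonlite::read_json("results/data/sweeps_truth.json",
                             simplifyVector = TRUE)

ov <- run_overlap(dcms, flk)
cat(sprintf("DCMS regions: %d; supported by FLK: %d (%.1f%%); shared %d bp\n",
            ov$n_a, ov$n_overlapping, 100 * ov$fraction, ov$shared_bp))

truth_regions <- data.frame(chrom = truth$chrom, start = truth$start_bp,
                            end = truth$end_bp)
ov_truth_d <- run_overlap(dcms, truth_regions)
ov_truth_f <- run_overlap(flk, truth_regions)
summary <- data.frame(
  comparison = c("DCMS_vs_FLK", "DCMS_vs_truth", "FLK_vs_truth"),
  n = c(ov$n_a, ov_truth_d$n_a, ov_truth_f$n_a),
  n_overlapping = c(ov$n_overlapping, ov_truth_d$n_overlapping,
                    ov_truth_f$n_overlapping),
  fraction = round(c(ov$fraction, ov_truth_d$fraction,
                     ov_truth_f$fraction), 4),
  shared_bp = c(ov$shared_bp, ov_truth_d$shared_bp, ov_truth_f$shared_bp))
print(summary)
utils::write.table(summary, "results/overlap_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
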