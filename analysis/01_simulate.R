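#!/usr/bin/env Rscript
# Build the synthetic study datasets the downstream scans analyse:
#   - a 4-breed neutral Balding-Nichols dataset (calibration baseline),
#   - the same genomes with 6 hard sweeps injected into chosen breeds,
#   - a 4-breed tree-drift dataset with known kinship,
#   - a toy gene annotation with one gene forced into every sweep window.
# Everything is written as plain text (VCF / TSV / GFF3 / JSON) under
# results/data/ so later stages exercise the package's readers.

suppressMessages(library(sweepscan))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2024L

cfg <- sim_config(n_breeds = 4, n_per_breed = 20, n_snps = 12000,
                  n_chroms = 3, drift = 0.05, seed = seed)
neutral <- simulate_neutral(cfg)$dataset
cat("neutral dataset: "); print(neutral)
write_vcf(neutral, file.path(out, "neutral.vcf"))
write_breed_table(neutral, file.path(out, "breeds.tsv"))

swept <- neutral
placements <- data.frame(chrom = c("1", "1", "2", "2", "3", "3"),
                         start = c(600L, 2600L, 1000L, 3000L, 1500L, 3400L),
                         breed = paste0("B", c(1, 2, 3, 4, 1, 3)))
for (i in seq_len(nrow(placements)))
  swept <- inject_sweep(swept,
                        sweep_spec(placements$chrom[i], placements$start[i],
                                   50, placements$breed[i], 0.95),
                        seed = seed + i)
truth <- attr(swept, "sweeps")
cat("injected", nrow(truth), "hard sweeps (50 SNPs, final frequency 0.95)\n")
print(truth)
write_vcf(swept, file.path(out, "swept.vcf"))
write_truth_json(truth, file.path(out, "sweeps_truth.json"))

ann <- make_annotation(swept$variants, 120, seed = seed + 100L,
                       truth_sweeps = truth, n_cluster_blocks = 2)
write_gene_annotation(ann, file.path(out, "genes.gff3"))
cat("annotation:", nrow(ann), "genes,",
    sum(grepl("^(KRT|HOXA)", ann$name)), "in clustered-prefix blocks\n")

nwk <- "((A:0.05,B:0.10):0.05,(C:0.05,D:0.10):0.05);"
treesim <- simulate_tree_drift(sim_config(n_breeds = 4, n_per_breed = 20,
                                          n_snps = 20000, n_chroms = 4,
                                          seed = seed + 200L), nwk)
write_vcf(treesim$dataset, file.path(out, "treedrift.vcf"))
write_breed_table(treesim$dataset, file.path(out, "treedrift_breeds.tsv"))
write_truth_json(list(newick = nwk, F = treesim$truth$F),
                 file.path(out, "treedrift_truth.json"))
cat("tree-drift dataset written; truth kinship diag:",
    paste(round(diag(treesim$truth$F), 3), collapse = " "), "\n")
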