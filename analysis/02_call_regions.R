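#!/usr/bin/env Rscript
# Stage 2: run the full detection pipeline over the stage-1 files.
#
# Calls HGT regions (identity >= 40% in >= 2 non-mammals, length > 1000 bp,
# <= 8 supporting mammals at > 40% coverage), sweeps the 3 x 3 threshold
# grid, and writes the composition tables, end-bias test and windowed
# profiles under results/run/.

suppressPackageStartupMessages(library(hgtscan))
seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L

d <- "results/data"
rc <- run_config(blocks = file.path(d, "blocks.tsv"),
                 panel = file.path(d, "panel.tsv"),
                 chrom_sizes = file.path(d, "genome.chrom.sizes"),
                 genome_fasta = file.path(d, "genome.fa"),
                 genes = file.path(d, "genes.bed"),
                 chromatin = file.path(d, "chromatin.bed"),
                 repeats = file.path(d, "repeats.bed"),
                 histone = file.path(d, "histone.bed"),
                 out_dir = "results/run", seed = seed)
res <- run_pipeline(rc)

truth <- read_regions_bed(file.path(d, "truth.bed"))
ev <- evaluate_calls(res$calls, truth)
message(sprintf("recovery vs planted truth: precision %.2f, recall %.2f",
                ev$precision, ev$recall))
message("threshold grid:")
print(res$grid)
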