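#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system.
#
# Emits a small focal genome (3 x 100 kb), a 41-mammal / 12-non-mammal
# species panel, annotation tracks, and a pairwise alignment-block table
# with 6 planted HGT regions on top of clade-structured background
# alignments. Everything downstream reads these files only.

suppressPackageStartupMessages(library(hgtscan))
seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L

cfg <- sim_config(seed = seed, n_chroms = 3, chrom_length = 100000,
                  n_planted_hgt = 6, background_block_rate = 0.1)
paths <- write_synthetic_dataset(cfg, "results/data")
message("simulated dataset under results/data (seed ", seed, "):")
message("  planted regions: ", nrow(paths$truth$regions))
message("  blocks table:    ", paths$blocks)
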