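#!/usr/bin/env Rscript
# Generate a synthetic ChIP-seq dataset with known ground truth.
#
# Emulates an F-plasmid-like experiment: one parS site with a 160-bp repeat
# region, a power-law flank, one roadblock locus (promoter-like exclusion,
# 80% suppression over 300 bp), triangular fragment smoothing (280 bp) and
# Poisson read noise at 100x anchor depth over an 80-kbp window. A second,
# fragment-free dataset is written for bp-resolution parameter recovery.

suppressPackageStartupMessages(library(parbcage))

seed <- 20
out_dir <- "results/synthetic"

roadblocks <- list(list(start_bp = 43000, end_bp = 43300, factor = 0.2))

truth_frag <- synthetic_truth(depth = 100, background = 10,
                              roadblocks = roadblocks, fragment_bp = 280,
                              seed = seed)
truth_bp <- synthetic_truth(depth = 100, background = 10,
                            roadblocks = roadblocks, fragment_bp = 0,
                            seed = seed)

ds_frag <- generate_dataset(truth_frag)
ds_bp <- generate_dataset(truth_bp)
write_dataset(ds_frag, out_dir, prefix = "fplasmid_frag280")
write_dataset(ds_bp, out_dir, prefix = "fplasmid_bp")

message(sprintf("IP mean %.1f reads/bp (fragment-smoothed), input mean %.1f",
                mean(ds_frag$ip$counts), mean(ds_frag$input$counts)))
message("Wrote bedGraph/BED/JSON under ", out_dir)
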