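#!/usr/bin/env Rscript
# Stage 1: build the synthetic stratified-lake community.
#
# Generates the default guild-structured community (60 epilimnion
# specialists, 30 hypolimnion specialists, 30 generalists, 6 cellular
# decoys) over 2 depths x 12 months, and writes the full table bundle
# (markers, checkm, lengths, samples, truth, abundance, counts, covfrac)
# that the later stages consume. Contig sequences are not materialized here;
# stage 2 builds a small sequence-bearing roster of its own.

suppressPackageStartupMessages(library(stratovir))

out <- "results/community"
cfg <- community_config(seed = 1L)
unlink(out, recursive = TRUE)
make_fixtures(cfg, out, sequences = FALSE)

truth <- read.delim(file.path(out, "truth.tsv"))
cat("community bundle written to", out, "\n")
print(table(truth$guild))
cat("samples: 24 (2 depths x 12 months), stratified May-Dec\n")
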