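#!/usr/bin/env Rscript
# Stage 5: habitat preference, persistence and the headline report.
#
# Classifies every genome by P_epi (cumulative stratified-period epilimnion
# share of RPKM; >0.95 epilimnion-specific, <0.05 hypolimnion-specific),
# scores each specialist's persistence (longest run of stratified months
# with covered fraction >20%) in its own layer, compares the groups with
# Welch's t-test, and reproduces the catalogue report percentages from the
# published counts.

suppressPackageStartupMessages(library(stratovir))

bundle <- "results/community"
lengths <- read.delim(file.path(bundle, "lengths.tsv"))
samples <- read.delim(file.path(bundle, "samples.tsv"))
truth <- read.delim(file.path(bundle, "truth.tsv"))
virus <- truth$mag_id[truth$guild != "cellular"]

load_matrix <- function(file) {
  df <- read.delim(file.path(bundle, file))
  key <- paste0(df$month, "_", ifelse(df$layer == "epilimnion", "epi", "hypo"))
  m <- matrix(0, length(virus), nrow(samples),
              dimnames = list(virus, samples$sample_id))
  keep <- df$mag_id %in% virus
  m[cbind(match(df$mag_id[keep], virus), match(key[keep], samples$sample_id))] <-
    df$value[keep]
  m
}

rp <- rpkm_matrix(load_matrix("counts.tsv"),
                  setNames(lengths$length_bp, lengths$mag_id))
covfrac <- load_matrix("covfrac.tsv")

calls <- habitat_calls(rp, samples)
write.table(calls, "results/habitat_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(table(calls$label))

guilds <- setNames(truth$guild, truth$mag_id)
want <- c(epi = "epilimnion-specific", hypo = "hypolimnion-specific")
spec <- names(guilds)[guilds %in% names(want)]
rec <- mean(calls$label[match(spec, calls$mag_id)] == want[guilds[spec]])
cat(sprintf("planted specialist labels recovered: %.1f%%\n", 100 * rec))

pc <- persistence_cohort(calls, covfrac, samples)
write.table(pc$table, "results/persistence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("median persistence: hypolimnion %g months vs epilimnion %g months\n",
            pc$medians[["hypolimnion-specific"]],
            pc$medians[["epilimnion-specific"]]))
cat(sprintf("Welch t-test on mean persistence: t = %.2f, p = %.2e\n",
            pc$welch$t, pc$welch$p_value))

# catalogue report percentages from the published counts
tab <- summary_percentages(n_total = 293, n_epi = 143, n_hypo = 49,
                           n_high_quality = 118, n_single_contig_hq = 42,
                           n_all_seven_hq = 74,
                           order_counts = c(Imitervirales = 237))
write.table(tab, "results/report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("catalogue report percentages:\n")
print(tab, row.names = FALSE)
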