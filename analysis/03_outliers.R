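#!/usr/bin/env Rscript
# Score mRNA and protein expression outliers for knowledgebase-linked
# features with the 1.5*IQR fence, rank them within samples, and resolve
# them to druggability calls.

suppressPackageStartupMessages(library(druggable))

sim <- "results/simulated"
out <- "results"
kb <- deduplicate_entries(load_knowledgebase(file.path(sim,
                                                       "knowledgebase.tsv")))
traits <- read_traits(file.path(sim, "traits.tsv"))

for (level in c("mrna", "protein")) {
  m <- read_expression_matrix(
    file.path(sim, paste0("expression_", level, ".tsv")), level = level)
  calls <- rank_within_sample(call_outliers(m, kb, traits))
  cat(level, ":", nrow(calls), "outlier calls across",
      length(unique(calls$feature)), "features\n")
  write.table(calls, file.path(out, paste0("outliers_", level, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dcalls <- annotate_outliers(calls, kb, traits)
  write.table(dcalls, file.path(out, paste0("outlier_calls_", level,
                                            ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
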