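#!/usr/bin/env Rscript
# Demographic enrichment of druggable genes: log2 odds matrix (clamped to
# +/-3) and Fisher exact tests with Benjamini-Hochberg FDR, for sex and
# race. Thresholds follow the druggability-demographics design: >= 20
# tumors per category per cancer type, genes druggable in >= 150 (sex) or
# >= 40 (race) tumors, >= 10 carriers per cell.

suppressPackageStartupMessages(library(druggable))

sim <- "results/simulated"
out <- "results"
traits <- read_traits(file.path(sim, "traits.tsv"))
read_calls <- function(f) {
  df <- read.delim(file.path(out, f), stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  df[!is.na(df$sample_id), , drop = FALSE]
}
all_calls <- rbind(read_calls("mutation_calls.tsv"),
                   read_calls("outlier_calls_mrna.tsv"),
                   read_calls("outlier_calls_protein.tsv"),
                   read_calls("putative_calls.tsv"))

for (trait in c("sex", "race")) {
  m <- build_demographic_matrix(all_calls, traits, trait = trait)
  res <- enrichment_tests(m)
  cat(trait, ":", nrow(res), "matrix cells,",
      sum(res$significant), "significant after FDR\n")
  write.table(res, file.path(out, paste0("demographics_", trait, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
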