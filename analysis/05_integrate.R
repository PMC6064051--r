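#!/usr/bin/env Rscript
# Integrate mutation, expression and putative cluster calls into per-tumor
# multi-omics druggability: profiles, the >= 2-data-type fraction,
# drug-class sectors with links, co-occurrence flags, and cumulative
# evidence-tier curves (hotspot3d below preclinical).

suppressPackageStartupMessages(library(druggable))

sim <- "results/simulated"
out <- "results"
kb <- deduplicate_entries(load_knowledgebase(file.path(sim,
                                                       "knowledgebase.tsv")))
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

mrna <- read_expression_matrix(file.path(sim, "expression_mrna.tsv"))
protein <- read_expression_matrix(file.path(sim, "expression_protein.tsv"))
records <- read.delim(file.path(out, "qc_records.tsv"),
                      stringsAsFactors = FALSE)
profiled <- list(mutation = unique(records$sample_id),
                 mrna = colnames(mrna), protein = colnames(protein))

profiles <- build_profiles(all_calls, profiled, traits)
mo <- multiomics_fraction(profiles)
cat(sprintf("%d of %d completely profiled tumors (%.1f%%) druggable on >= 2 data types\n",
            mo$n_multiomics, mo$n_total, 100 * mo$fraction))
write.table(profiles, file.path(out, "profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sect <- drug_class_sectors(all_calls, kb, synthetic_viz_classes())
cat(nrow(sect$cross_links), "cross-class links,",
    nrow(sect$within_links), "within-class multi-biomarker links\n")
write.table(sect$sectors, file.path(out, "sectors.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sect$cross_links, file.path(out, "cross_links.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sect$within_links, file.path(out, "within_links.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cooc <- cooccurrence_report(all_calls, kb)
flagged <- cooc[cooc$flag != "none", ]
cat(sum(flagged$flag == "sensitive_resistant"),
    "sensitive+resistant pairs (therapy-failure risk),",
    sum(flagged$flag == "combination_candidate"),
    "combination candidates\n")
write.table(cooc, file.path(out, "cooccurrence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cum <- cumulative_tier_summary(all_calls, traits)
write.table(cum, file.path(out, "cumulative_tiers.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
nons <- cum[cum$setting == "non_specific", ]
cat("cumulative non-specific fractions:",
    paste(sprintf("%s=%.3f", nons$tier, nons$cumulative_fraction),
          collapse = " "), "\n")
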