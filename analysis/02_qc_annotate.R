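#!/usr/bin/env Rscript
# QC the simulated cohort and match mutations against the knowledgebase:
# duplicate-sample removal, indel and common-variant filters, then
# per-sample druggability calls and the cumulative evidence-tier table.

suppressPackageStartupMessages(library(druggable))

sim <- "results/simulated"
out <- "results"
kb <- deduplicate_entries(load_knowledgebase(file.path(sim,
                                                       "knowledgebase.tsv")))
records <- read_maf(file.path(sim, "mutations.maf.tsv"))
qc <- qc_cohort(records)
cat("QC kept", nrow(qc$records), "of", nrow(records), "records; dropped",
    nrow(qc$removed), "near-duplicate sample(s)\n")
write.table(qc$records, file.path(out, "qc_records.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

calls <- annotate_cohort(qc$records, kb)
traits <- read_traits(file.path(sim, "traits.tsv"))
cat(nrow(calls), "druggability calls in",
    length(unique(calls$sample_id)), "samples;",
    sum(calls$specificity == "cancer_type_specific"),
    "are cancer-type specific\n")
write.table(calls, file.path(out, "mutation_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tiers <- summarize_mutation_druggability(calls, traits)
write.table(tiers, file.path(out, "mutation_tiers.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
fda <- tiers[tiers$tier == "fda_approved" & tiers$setting == "specific", ]
cat("specific FDA-tier fractions by cancer type:",
    paste(sprintf("%s=%.2f", fda$cancer_type, fda$cumulative_fraction),
          collapse = " "), "\n")
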