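#!/usr/bin/env Rscript
# Validate biomarkers against the simulated cell-line screen: pooled and
# per-combination Mann-Whitney LN(IC50) comparisons, and per-probe
# outlier-score regressions with the P < 0.05 & B < 0 rule.

suppressPackageStartupMessages(library(druggable))

sim <- "results/simulated"
out <- "results"
kb <- deduplicate_entries(load_knowledgebase(file.path(sim,
                                                       "knowledgebase.tsv")))
screen <- read_screen(file.path(sim, "screen.tsv"))
cl_maf <- read.delim(file.path(sim, "cell_line_mutations.tsv"),
                     stringsAsFactors = FALSE)
screen_drugs <- read.delim(file.path(sim, "screen_drugs.tsv"),
                           stringsAsFactors = FALSE)
probe_map <- read.delim(file.path(sim, "probe_map.tsv"),
                        stringsAsFactors = FALSE)
expr_df <- read.delim(file.path(sim, "cell_line_expression.tsv"),
                      check.names = FALSE, stringsAsFactors = FALSE)
cl_expr <- as.matrix(expr_df[, -1])
rownames(cl_expr) <- expr_df[[1]]

dm <- map_drugs(unique(kb$drug), screen_drugs)
cat(nrow(dm$map), "knowledgebase drugs mapped to screened compounds;",
    length(dm$unmapped), "unmapped\n")

for (setting in c("non_specific", "specific")) {
  res <- mutation_sensitivity_test(screen, kb, cl_maf, dm$map,
                                   setting = setting)
  cat(sprintf("%s: pooled n=%d, Mann-Whitney p=%.3g; %d eligible combinations, %d with p<0.05\n",
              setting, res$global$n, res$global$p_value,
              nrow(res$per_combination),
              sum(res$per_combination$p_value < 0.05)))
  write.table(res$per_combination,
              file.path(out, paste0("screen_combinations_", setting,
                                    ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

reg <- expression_sensitivity_regression(screen, cl_expr, probe_map, kb,
                                         dm$map)
cat(nrow(reg$regressions), "probe-drug regressions;",
    sum(reg$regressions$significant), "significant (p<0.05, B<0);",
    "validated genes:", paste(reg$validated_genes, collapse = ", "), "\n")
write.table(reg$regressions, file.path(out, "screen_regressions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
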