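#!/usr/bin/env Rscript
# Generate the synthetic study inputs: knowledgebase, MAF, expression
# matrices, traits, a residue-distance structure, and a cell-line screen,
# with ground-truth tables. Downstream scripts read from results/simulated/.

suppressPackageStartupMessages(library(druggable))

args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 1) args[1] else 1)
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
sim <- simulate_cohort(cfg, out_dir = out)
cat("cohort:", length(unique(sim$traits$sample_id)), "samples,",
    nrow(sim$maf), "mutation rows,",
    nrow(sim$truth$druggable), "planted knowledgebase-druggable events\n")

st <- simulate_structure(cfg)
write.table(st$distances, file.path(out, "structure_distances.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("structure:", cfg$structure$structure_id, "with hotspot residues",
    paste(st$truth$hotspots[[1]], collapse = ", "), "\n")

sc <- simulate_screen(cfg)
write.table(sc$screen, file.path(out, "screen.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sc$cl_maf, file.path(out, "cell_line_mutations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(probe_id = rownames(sc$cl_expr), sc$cl_expr,
                       check.names = FALSE),
            file.path(out, "cell_line_expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sc$probe_map, file.path(out, "probe_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sc$screen_drugs, file.path(out, "screen_drugs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("screen:", length(unique(sc$screen$cell_line_id)), "cell lines x",
    length(unique(sc$screen$drug_id)), "drugs\n")
cat("inputs written to", out, "(seed", seed, ")\n")
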