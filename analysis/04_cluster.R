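#!/usr/bin/env Rscript
# Recursive 3D proximity clustering on the simulated structure: empirical
# pair p-values, single-link components, centroid focusing at a 5 A graph
# radius, then label propagation to nominate putative drug-response
# mutations and lift them to tumor-level calls.

suppressPackageStartupMessages(library(druggable))

sim <- "results/simulated"
out <- "results"
kb <- deduplicate_entries(load_knowledgebase(file.path(sim,
                                                       "knowledgebase.tsv")))
records <- read.delim(file.path(out, "qc_records.tsv"),
                      stringsAsFactors = FALSE)
distances <- read_distance_table(file.path(sim, "structure_distances.tsv"))
gene <- unique(distances$gene)

muts <- structure_mutations(records, kb, gene)
clusters <- cluster_structure(distances, muts)
cat(length(unique(clusters$cluster_id)), "cluster(s) on", gene,
    "covering", nrow(clusters), "mutated residues\n")
write.table(clusters, file.path(out, "clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

putative <- propagate_labels(clusters)
cat(nrow(putative), "putative drug-response mutation(s):",
    paste(putative$mutation, collapse = ", "), "\n")
write.table(putative, file.path(out, "putative_mutations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pcalls <- putative_druggability_calls(putative, records)
cat(nrow(pcalls), "tumor-level putative calls at the hotspot3d tier\n")
write.table(pcalls, file.path(out, "putative_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
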