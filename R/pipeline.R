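# End-to-end pipeline driver: simulate -> QC -> annotate -> outliers ->
# cluster -> integrate -> screen-validate -> demographics, returning every
# intermediate table. Used by the analysis scripts and by the determinism
# check (two runs at one seed must produce byte-identical outputs).

#' Build the mutation table for one gene's structure clustering
#'
#' Unique mutations of `gene` in the cohort with their residue position,
#' sample recurrence, and knowledgebase label (effect of the resolved match,
#' NA for uncatalogued mutations) plus the matched drug.
#'
#' @param records QC'd cohort mutation records.
#' @param kb Resolved knowledgebase.
#' @param gene Gene symbol.
#' @return data.frame: residue, mutation, recurrence, kb_label, drug.
#' @export
structure_mutations <- function(records, kb, gene) {
  sub <- records[records$gene == gene, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(empty_df(c("residue", "mutation", "recurrence", "kb_label",
                      "drug")))
  index <- build_kb_index(kb)
  muts <- unique(sub$protein_change)
  out <- list()
  for (m in muts) {
    pc <- parse_protein_change(m)
    if (!pc$ok || is.na(pc$pos)) next
    rec_i <- sub[sub$protein_change == m, , drop = FALSE][1, , drop = FALSE]
    hits <- match_mutation(rec_i, kb, index)
    if (length(hits) > 0L) {
      call <- resolve_call(rec_i, hits, kb, rec_i$cancer_type)
      label <- call$effect
      drug <- call$chosen_drug
    } else {
      label <- NA_character_
      drug <- NA_character_
    }
    out[[length(out) + 1L]] <- data.frame(
      residue = pc$pos, mutation = m,
      recurrence = length(unique(sub$sample_id[sub$protein_change == m])),
      kb_label = label, drug = drug, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(empty_df(c("residue", "mutation", "recurrence", "kb_label",
                      "drug")))
  res <- do.call(rbind, out)
  # one mutation per residue for clustering: keep the most recurrent,
  # preferring labeled (knowledgebase) mutations on ties
  res <- res[order(res$residue, is.na(res$kb_label), -res$recurrence,
                   res$mutation), , drop = FALSE]
  res <- res[!duplicated(res$residue), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a cohort, structure and screen from `config`, round-trips the
#' cohort files through the package readers, and runs every analysis stage.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, every result table is
#'   written there as TSV (stable column and row order).
#' @return Named list of result tables and summary objects.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL) {
  io_dir <- file.path(tempfile("druggable_sim_"))
  sim <- simulate_cohort(config, out_dir = io_dir)
  kb <- suppressMessages(
    load_knowledgebase(file.path(io_dir, "knowledgebase.tsv")))
  kb <- deduplicate_entries(kb)
  records <- read_maf(file.path(io_dir, "mutations.maf.tsv"))
  qc <- suppressMessages(qc_cohort(records))
  traits <- read_traits(file.path(io_dir, "traits.tsv"))
  mrna <- read_expression_matrix(file.path(io_dir, "expression_mrna.tsv"),
                                 level = "mrna")
  protein <- read_expression_matrix(
    file.path(io_dir, "expression_protein.tsv"), level = "protein")
  unlink(io_dir, recursive = TRUE)

  mutation_calls <- annotate_cohort(qc$records, kb)
  out_mrna <- rank_within_sample(
    suppressMessages(call_outliers(mrna, kb, traits)))
  out_protein <- rank_within_sample(
    suppressMessages(call_outliers(protein, kb, traits)))
  mrna_calls <- annotate_outliers(out_mrna, kb, traits)
  protein_calls <- annotate_outliers(out_protein, kb, traits)

  st <- simulate_structure(config)
  muts <- structure_mutations(qc$records, kb, config$structure$gene)
  clusters <- cluster_structure(st$distances, muts)
  putative <- suppressWarnings(propagate_labels(clusters))
  putative_calls <- putative_druggability_calls(putative, qc$records)

  all_calls <- rbind(mutation_calls, mrna_calls, protein_calls,
                     putative_calls)
  profiled <- list(mutation = unique(records$sample_id),
                   mrna = colnames(mrna), protein = colnames(protein))
  profiles <- suppressWarnings(
    build_profiles(all_calls, profiled, traits))
  mo <- multiomics_fraction(profiles)
  sectors <- drug_class_sectors(all_calls, kb, synthetic_viz_classes())
  cooccurrence <- cooccurrence_report(all_calls, kb)
  cumulative <- cumulative_tier_summary(all_calls, traits)
  tier_table <- summarize_mutation_druggability(mutation_calls, traits)

  sc <- simulate_screen(config, kb)
  mw <- suppressWarnings(
    mutation_sensitivity_test(sc$screen, kb, sc$cl_maf, sc$drug_map))
  reg <- expression_sensitivity_regression(sc$screen, sc$cl_expr,
                                           sc$probe_map, kb, sc$drug_map)
  demo_sex <- enrichment_tests(
    build_demographic_matrix(all_calls, traits, trait = "sex"))

  result <- list(
    qc_records = qc$records, qc_removed = qc$removed,
    mutation_calls = mutation_calls, outliers_mrna = out_mrna,
    outliers_protein = out_protein, clusters = clusters,
    putative = putative, putative_calls = putative_calls,
    all_calls = all_calls, profiles = profiles,
    multiomics = data.frame(fraction = mo$fraction,
                            n_multiomics = mo$n_multiomics,
                            n_total = mo$n_total),
    sectors = sectors$sectors, cross_links = sectors$cross_links,
    within_links = sectors$within_links, cooccurrence = cooccurrence,
    cumulative_tiers = cumulative, mutation_tiers = tier_table,
    screen_global = data.frame(n = mw$global$n,
                               statistic = mw$global$statistic,
                               p_value = mw$global$p_value),
    screen_combinations = mw$per_combination,
    screen_regressions = reg$regressions,
    validated_genes = data.frame(gene = reg$validated_genes),
    demographics_sex = demo_sex,
    truth_druggable = sim$truth$druggable)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(result)) {
      if (is.data.frame(result[[nm]]))
        write_tsv_file(result[[nm]], file.path(out_dir,
                                               paste0(nm, ".tsv")))
    }
  }
  result
}
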