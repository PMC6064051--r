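# In-code fixture builders shared across test files.

kb_entry <- function(gene, vc, spec, tt, eff, lvl, drug,
                     cls = "classX", pmid = "t") {
  data.frame(gene = gene, variant_class = vc, variant_spec = spec,
             tumor_type = tt, effect = eff, evidence_level = lvl,
             drug = drug, drug_classes = cls, pubmed_id = pmid,
             stringsAsFactors = FALSE)
}

kb_table <- function(...) {
  kb <- rbind(...)
  kb$entry_id <- seq_len(nrow(kb))
  kb
}

write_kb_tsv <- function(kb, path = tempfile(fileext = ".tsv")) {
  cols <- c("gene", "variant_class", "variant_spec", "tumor_type", "effect",
            "evidence_level", "drug", "drug_classes", "pubmed_id")
  utils::write.table(kb[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

mut_record <- function(sample_id, gene, pc, cls = "missense", ct = "CT1",
                       indel = 0L, af = NA_real_, path = TRUE) {
  data.frame(sample_id = sample_id, cancer_type = ct, gene = gene,
             protein_change = pc, mutation_class = cls,
             indel_length = indel, population_af = af,
             pathogenic_flag = path, stringsAsFactors = FALSE)
}

maf_row <- function(sample, gene, pc, vc = "Missense_Mutation",
                    indel = 0L, af = NA_real_, path = FALSE, ct = "CT1") {
  data.frame(Tumor_Sample_Barcode = sample, Hugo_Symbol = gene,
             Variant_Classification = vc,
             HGVSp_Short = paste0("p.", pc), Indel_Length = indel,
             Population_AF = af, Pathogenic_Flag = path, Cancer_Type = ct,
             stringsAsFactors = FALSE)
}

write_maf_tsv <- function(maf, path = tempfile(fileext = ".tsv")) {
  utils::write.table(maf, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

druggability_call <- function(sample_id, gene, variant_key,
                              data_level = "mutation",
                              effect = "sensitive",
                              specificity = "non_specific",
                              drug = "drugA", evidence = "fda_approved",
                              ct = "CT1") {
  data.frame(sample_id = sample_id, cancer_type = ct, gene = gene,
             variant_key = variant_key, data_level = data_level,
             effect = effect, specificity = specificity,
             chosen_drug = drug, chosen_evidence = evidence,
             all_matches = "", stringsAsFactors = FALSE)
}
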