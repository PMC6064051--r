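# Cohort input/output and QC. Somatic mutations arrive in a MAF-dialect TSV
# already annotated at the protein level (one canonical isoform per gene)
# with population allele frequency and a precomputed pathogenicity flag.
# The QC filters remove large/complex indels, near-duplicate samples, and
# common non-pathogenic variants.

MAF_REQUIRED <- c("Tumor_Sample_Barcode", "Hugo_Symbol",
                  "Variant_Classification", "HGVSp_Short", "Indel_Length",
                  "Population_AF", "Pathogenic_Flag", "Cancer_Type")

MAF_CLASS_MAP <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Frame_Shift_Del   = "frameshift",
  Frame_Shift_Ins   = "frameshift",
  In_Frame_Del      = "inframe_del",
  In_Frame_Ins      = "inframe_ins"
)

#' Read a MAF-dialect somatic mutation table
#'
#' Required columns: Tumor_Sample_Barcode, Hugo_Symbol,
#' Variant_Classification, HGVSp_Short, Indel_Length, Population_AF,
#' Pathogenic_Flag, Cancer_Type. Lines starting with '#' are comments.
#' Unparseable protein changes are kept with `mutation_class = "other"` and
#' a warning.
#'
#' @param path Path to the MAF TSV.
#' @return data.frame of mutation records with columns sample_id,
#'   cancer_type, gene, protein_change, mutation_class, indel_length,
#'   population_af, pathogenic_flag (plus variant_type if present in the
#'   input).
#' @export
read_maf <- function(path) {
  df <- read_tsv_file(path, required = MAF_REQUIRED)
  out <- data.frame(
    sample_id = as.character(df$Tumor_Sample_Barcode),
    cancer_type = as.character(df$Cancer_Type),
    gene = as.character(df$Hugo_Symbol),
    protein_change = sub("^p\\.", "", as.character(df$HGVSp_Short)),
    mutation_class = unname(MAF_CLASS_MAP[as.character(df$Variant_Classification)]),
    indel_length = as.integer(df$Indel_Length),
    population_af = as.numeric(df$Population_AF),
    pathogenic_flag = as.logical(df$Pathogenic_Flag),
    stringsAsFactors = FALSE
  )
  out$mutation_class[is.na(out$mutation_class)] <- "other"
  out$indel_length[is.na(out$indel_length)] <- 0L
  if ("Variant_Type" %in% names(df))
    out$variant_type <- as.character(df$Variant_Type)
  # protein changes must parse for classes where matching relies on position
  needs_parse <- out$mutation_class %in%
    c("missense", "inframe_del", "inframe_ins")
  if (any(needs_parse)) {
    bad <- needs_parse & !vapply(out$protein_change,
                                 function(p) parse_protein_change(p)$ok,
                                 logical(1))
    if (any(bad)) {
      warning(sum(bad), " record(s) with unparseable protein change kept ",
              "with mutation_class = 'other'", call. = FALSE)
      out$mutation_class[bad] <- "other"
    }
  }
  out
}

#' Remove large and complex indels
#'
#' Indels longer than 100 bp are removed (strict inequality: a 100 bp indel
#' is kept). Rows whose `variant_type` is one of `complex_tokens` are also
#' removed when that column is present.
#'
#' @param records Mutation records from [read_maf()].
#' @param max_indel_bp Size threshold in bp (default 100).
#' @param complex_tokens Variant_Type values treated as complex indels.
#' @return Filtered records; the removal count is reported via `message()`.
#' @export
filter_large_complex_indels <- function(records, max_indel_bp = 100L,
                                        complex_tokens = c("Complex")) {
  drop <- records$indel_length > max_indel_bp
  if ("variant_type" %in% names(records))
    drop <- drop | records$variant_type %in% complex_tokens
  message("filter_large_complex_indels: removed ", sum(drop), " of ",
          nrow(records), " records")
  records[!drop, , drop = FALSE]
}

# Internal: per-sample sets of variant keys
sample_variant_sets <- function(records) {
  key <- paste(records$gene, records$protein_change, sep = ":")
  split(key, records$sample_id)
}

#' Remove near-duplicate tumor samples
#'
#' For each pair of samples with variant concordance > `max_concordance`,
#' one sample is dropped unless both samples have `small_sample_max` or
#' fewer total variants. Concordance is the shared-variant count divided by
#' the smaller sample's variant count. Of a flagged pair, the sample with
#' fewer variants is dropped; on a tie, the lexicographically later barcode.
#'
#' @param records Mutation records.
#' @param max_concordance Concordance threshold (default 0.60, strict `>`).
#' @param small_sample_max Pairs where both samples have at most this many
#'   variants are exempt (default 5).
#' @return List with `records` (filtered) and `removed` (data.frame of
#'   dropped sample ids with the partner that flagged them).
#' @export
remove_duplicate_samples <- function(records, max_concordance = 0.60,
                                     small_sample_max = 5L) {
  sets <- sample_variant_sets(records)
  ids <- sort(names(sets))
  dropped <- character(0)
  partner <- character(0)
  if (length(ids) > 1L) {
    for (a_i in seq_len(length(ids) - 1L)) {
      a <- ids[a_i]
      if (a %in% dropped) next
      for (b in ids[(a_i + 1L):length(ids)]) {
        if (b %in% dropped || a %in% dropped) next
        na <- length(unique(sets[[a]])); nb <- length(unique(sets[[b]]))
        if (na <= small_sample_max && nb <= small_sample_max) next
        shared <- length(intersect(unique(sets[[a]]), unique(sets[[b]])))
        conc <- shared / min(na, nb)
        if (conc > max_concordance) {
          drop_id <- if (na < nb) a else if (nb < na) b else max(a, b)
          dropped <- c(dropped, drop_id)
          partner <- c(partner, setdiff(c(a, b), drop_id))
        }
      }
    }
  }
  removed <- data.frame(sample_id = dropped, concordant_with = partner,
                        stringsAsFactors = FALSE)
  if (nrow(removed) > 0L)
    message("remove_duplicate_samples: dropped ",
            paste(dropped, collapse = ", "))
  list(records = records[!records$sample_id %in% dropped, , drop = FALSE],
       removed = removed)
}

#' Remove common non-pathogenic variants
#'
#' Records with population minor allele frequency above `max_af` that are
#' not flagged pathogenic are removed. A missing allele frequency is treated
#' as rare (kept).
#'
#' @param records Mutation records.
#' @param max_af Population AF threshold as a fraction (default 0.0005,
#'   i.e. 0.05%).
#' @return Filtered records.
#' @export
filter_common_variants <- function(records, max_af = 5e-4) {
  drop <- !is.na(records$population_af) &
    records$population_af > max_af &
    !records$pathogenic_flag
  message("filter_common_variants: removed ", sum(drop), " of ",
          nrow(records), " records")
  records[!drop, , drop = FALSE]
}

#' Run the full cohort QC chain
#'
#' Applies, in order: large/complex indel removal, duplicate-sample removal,
#' and common-variant removal.
#'
#' @param records Mutation records from [read_maf()].
#' @inheritParams filter_large_complex_indels
#' @inheritParams remove_duplicate_samples
#' @inheritParams filter_common_variants
#' @return List with `records` and the duplicate-sample `removed` report.
#' @export
qc_cohort <- function(records, max_indel_bp = 100L,
                      complex_tokens = c("Complex"),
                      max_concordance = 0.60, small_sample_max = 5L,
                      max_af = 5e-4) {
  records <- filter_large_complex_indels(records, max_indel_bp,
                                         complex_tokens)
  dup <- remove_duplicate_samples(records, max_concordance, small_sample_max)
  records <- filter_common_variants(dup$records, max_af)
  list(records = records, removed = dup$removed)
}

#' Read a gene (or phosphosite) by sample expression matrix
#'
#' First column holds the row label (gene symbol, or `GENE:pSNNN` for a
#' phosphosite); remaining columns are sample barcodes. Duplicate row labels
#' are an error.
#'
#' @param path TSV path.
#' @param level One of "mrna", "protein", "phosphoprotein" (recorded as an
#'   attribute).
#' @param log2_transform Apply log2(x + 1); conventionally used for
#'   RSEM-like mRNA values arriving on the raw scale.
#' @return Numeric matrix with features as rows and samples as columns;
#'   attribute `level` records the data level.
#' @export
read_expression_matrix <- function(path, level = c("mrna", "protein",
                                                   "phosphoprotein"),
                                   log2_transform = FALSE) {
  level <- match.arg(level)
  df <- read_tsv_file(path)
  labels <- as.character(df[[1]])
  if (anyDuplicated(labels))
    stop("duplicate row labels in expression matrix: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  if (log2_transform) m <- log2(m + 1)
  attr(m, "level") <- level
  m
}

#' Read per-sample clinical traits
#'
#' @param path TSV with columns sample_id, cancer_type, sex, race.
#' @return data.frame; sample_id must be unique.
#' @export
read_traits <- function(path) {
  df <- read_tsv_file(path, required = c("sample_id", "cancer_type",
                                         "sex", "race"))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in traits table", call. = FALSE)
  df
}
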