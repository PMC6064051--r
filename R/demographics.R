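# Demographic enrichment of druggability. For each eligible cancer type and
# commonly druggable gene, a log2 odds ratio contrasts the druggable
# fraction between two demographic categories, with infinities clamped to
# +/-3 for display; Fisher exact tests with Benjamini-Hochberg FDR assess
# significance.

# Cancer types excluded from the sex analysis (sex-specific organs)
SEX_SPECIFIC_CANCER_TYPES <- c("BRCA", "CESC", "PRAD", "OV", "UCEC", "UCS")

#' Build the demographics log-odds matrix
#'
#' Eligibility: cancer types with at least `min_per_category` tumors in each
#' of the two contrasted categories; genes druggable (sensitive call on any
#' data level) in at least `min_gene_tumors` tumors cohort-wide (defaults:
#' 150 for sex, 40 for race); a (cancer type, gene) cell is computed only
#' when at least `min_cell` tumors of that cancer type carry the druggable
#' gene. log odds = log2((dA/nA)/(dB/nB)); +/-Inf clamps to +/-3. The sex
#' analysis drops sex-specific cancer types.
#'
#' @param calls Combined druggability calls (sensitive calls define
#'   "druggable in gene").
#' @param traits Traits table (sample_id, cancer_type, sex, race).
#' @param trait "sex" or "race".
#' @param categories Optional length-2 character vector fixing the A/B
#'   categories; default contrasts the two largest categories.
#' @param min_per_category,min_gene_tumors,min_cell Thresholds as above;
#'   `min_gene_tumors = NULL` picks 150 (sex) or 40 (race).
#' @param exclude_cancer_types Cancer types dropped before analysis;
#'   defaults to the sex-specific list for the sex trait, none for race.
#' @return data.frame of cells: cancer_type, gene, trait_a, trait_b, dA,
#'   nA, dB, nB, log_odds (clamped).
#' @export
build_demographic_matrix <- function(calls, traits,
                                     trait = c("sex", "race"),
                                     categories = NULL,
                                     min_per_category = 20L,
                                     min_gene_tumors = NULL,
                                     min_cell = 10L,
                                     exclude_cancer_types = NULL) {
  trait <- match.arg(trait)
  if (is.null(min_gene_tumors))
    min_gene_tumors <- if (trait == "sex") 150L else 40L
  if (is.null(exclude_cancer_types))
    exclude_cancer_types <- if (trait == "sex")
      SEX_SPECIFIC_CANCER_TYPES else character(0)
  if (length(unique(stats::na.omit(traits[[trait]]))) < 2L)
    stop("trait '", trait, "' has fewer than 2 categories", call. = FALSE)
  tr <- traits[!is.na(traits[[trait]]) &
                 !traits$cancer_type %in% exclude_cancer_types, ,
               drop = FALSE]
  empty_cells <- empty_df(c("cancer_type", "gene", "trait_a", "trait_b",
                            "dA", "nA", "dB", "nB", "log_odds"))
  if (is.null(categories)) {
    cats <- unique(tr[[trait]])
    if (length(cats) < 2L) return(empty_cells)
    counts <- table(tr[[trait]])[cats]
    # two largest categories; ties broken by first appearance in traits
    categories <- cats[order(-as.integer(counts))][1:2]
  }
  a <- categories[1]; b <- categories[2]
  tr <- tr[tr[[trait]] %in% categories, , drop = FALSE]
  sens <- calls[calls$effect == "sensitive", , drop = FALSE]
  # genes druggable in enough tumors cohort-wide
  gene_n <- tapply(sens$sample_id, sens$gene,
                   function(s) length(unique(s)))
  genes <- sort(names(gene_n)[gene_n >= min_gene_tumors])
  out <- list()
  for (ct in sort(unique(tr$cancer_type))) {
    sub <- tr[tr$cancer_type == ct, , drop = FALSE]
    nA <- sum(sub[[trait]] == a); nB <- sum(sub[[trait]] == b)
    if (nA < min_per_category || nB < min_per_category) next
    for (g in genes) {
      carriers <- unique(sens$sample_id[sens$gene == g])
      ct_carriers <- intersect(carriers, sub$sample_id)
      if (length(ct_carriers) < min_cell) next
      dA <- sum(sub$sample_id %in% carriers & sub[[trait]] == a)
      dB <- sum(sub$sample_id %in% carriers & sub[[trait]] == b)
      lo <- log2((dA / nA) / (dB / nB))
      if (is.infinite(lo)) lo <- sign(lo) * 3
      out[[length(out) + 1L]] <- data.frame(
        cancer_type = ct, gene = g, trait_a = a, trait_b = b,
        dA = dA, nA = nA, dB = dB, nB = nB, log_odds = lo,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_cells)
  do.call(rbind, out)
}

#' Fisher exact enrichment tests with FDR over the demographics matrix
#'
#' Two-sided Fisher exact test per cell on the 2x2 table
#' [[dA, nA-dA], [dB, nB-dB]]; Benjamini-Hochberg q-values across all cells
#' of the matrix; significant iff q < `fdr_cutoff`.
#'
#' @param matrix_df Matrix cells from [build_demographic_matrix()].
#' @param fdr_cutoff Significance cutoff on q (default 0.05).
#' @return `matrix_df` with fisher_p, fdr_q and significant columns.
#' @export
enrichment_tests <- function(matrix_df, fdr_cutoff = 0.05) {
  if (nrow(matrix_df) == 0L) {
    matrix_df$fisher_p <- numeric(0)
    matrix_df$fdr_q <- numeric(0)
    matrix_df$significant <- logical(0)
    return(matrix_df)
  }
  matrix_df$fisher_p <- vapply(seq_len(nrow(matrix_df)), function(i) {
    tab <- matrix(c(matrix_df$dA[i], matrix_df$nA[i] - matrix_df$dA[i],
                    matrix_df$dB[i], matrix_df$nB[i] - matrix_df$dB[i]),
                  nrow = 2, byrow = TRUE)
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }, numeric(1))
  matrix_df$fdr_q <- stats::p.adjust(matrix_df$fisher_p, method = "BH")
  matrix_df$significant <- matrix_df$fdr_q < fdr_cutoff
  matrix_df
}
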