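# Cell-line drug-screen validation. Biomarkers are validated two ways:
# (i) LN(IC50) distributions of lines carrying knowledgebase mutations are
# compared to a background of every drug-cell-line measurement with the
# Mann-Whitney U test (globally, and per mutation/drug combination with at
# least five carrier lines); (ii) per-probe ordinary least squares of
# LN(IC50) on the expression outlier score, a gene counting as validated
# when at least one probe has p < 0.05 with a negative slope. No
# multiple-testing correction is applied to the probe/drug family, matching
# the validation design this mirrors; treat the per-combination p-values as
# descriptive.

#' Read a cell-line drug screen table
#'
#' @param path TSV with columns cell_line_id, tissue_type, drug_id,
#'   ln_ic50 (and optionally auc). One row per (cell line, drug) pair.
#' @return data.frame.
#' @export
read_screen <- function(path) {
  df <- read_tsv_file(path, required = c("cell_line_id", "tissue_type",
                                         "drug_id", "ln_ic50"))
  df$ln_ic50 <- as.numeric(df$ln_ic50)
  if (anyDuplicated(paste(df$cell_line_id, df$drug_id)))
    stop("duplicate (cell_line, drug) pairs in screen", call. = FALSE)
  df
}

#' Map knowledgebase drugs to screened compounds
#'
#' A knowledgebase drug maps to a screened compound if its name matches the
#' compound's name or a synonym case-insensitively, or if a target gene of
#' the drug matches a target of the compound.
#'
#' @param kb_drugs Character vector of knowledgebase drug names.
#' @param screen_drugs data.frame with columns drug_id, drug_name,
#'   synonyms (';'-separated, may be empty), targets (';'-separated).
#' @param kb_targets Optional data.frame (drug, target) giving target genes
#'   for knowledgebase drugs; without it only name/synonym matching runs.
#' @return List with `map` (data.frame kb_drug, drug_id, matched_by) and
#'   `unmapped` (character vector).
#' @export
map_drugs <- function(kb_drugs, screen_drugs, kb_targets = NULL) {
  kb_drugs <- unique(kb_drugs)
  norm <- function(x) tolower(trimws(x))
  rows <- list()
  for (d in kb_drugs) {
    for (i in seq_len(nrow(screen_drugs))) {
      names_i <- c(screen_drugs$drug_name[i],
                   strsplit(if (is.na(screen_drugs$synonyms[i])) ""
                            else screen_drugs$synonyms[i], ";")[[1]])
      by <- NULL
      if (norm(d) %in% norm(names_i[nzchar(names_i)])) {
        by <- "name"
      } else if (!is.null(kb_targets)) {
        tg_kb <- kb_targets$target[norm(kb_targets$drug) == norm(d)]
        tg_sc <- strsplit(if (is.na(screen_drugs$targets[i])) ""
                          else screen_drugs$targets[i], ";")[[1]]
        if (length(intersect(tg_kb, tg_sc)) > 0L) by <- "target"
      }
      if (!is.null(by)) {
        rows[[length(rows) + 1L]] <- data.frame(
          kb_drug = d, drug_id = screen_drugs$drug_id[i], matched_by = by,
          stringsAsFactors = FALSE)
      }
    }
  }
  map <- if (length(rows) > 0L) do.call(rbind, rows) else
    empty_df(c("kb_drug", "drug_id", "matched_by"))
  list(map = map, unmapped = setdiff(kb_drugs, map$kb_drug))
}

#' Mann-Whitney tests of LN(IC50) for knowledgebase mutations
#'
#' The global test pools LN(IC50) of every (carrier line, mapped drug)
#' measurement and compares it, two-sided, against the full background of
#' all measurements (the background includes the carriers). Per
#' (mutation, drug) combinations with at least `min_lines` carrier lines
#' are tested against that drug's own background across all lines.
#'
#' @param screen Screen table from [read_screen()].
#' @param kb Resolved knowledgebase.
#' @param cl_records Cell-line mutation records (MAF dialect: sample_id is
#'   the cell line, cancer_type its tissue type).
#' @param drug_map Mapping from [map_drugs()]`$map`.
#' @param setting "specific" restricts to calls whose tissue attains the
#'   maximal evidence; "non_specific" (default) uses all calls.
#' @param min_lines Minimum carrier lines per combination (default 5).
#' @return List with `global` (n, statistic, p_value) and `per_combination`
#'   (data.frame variant_key, drug_id, n, statistic, p_value).
#' @export
mutation_sensitivity_test <- function(screen, kb, cl_records, drug_map,
                                      setting = c("non_specific",
                                                  "specific"),
                                      min_lines = 5L) {
  setting <- match.arg(setting)
  calls <- annotate_cohort(cl_records, kb)
  if (setting == "specific")
    calls <- calls[calls$specificity == "cancer_type_specific", ,
                   drop = FALSE]
  background <- screen$ln_ic50
  per_cols <- c("variant_key", "drug_id", "n", "statistic", "p_value")
  if (nrow(calls) == 0L) {
    warning("no eligible cell lines in the ", setting, " setting",
            call. = FALSE)
    return(list(global = list(n = 0L, statistic = NA_real_,
                              p_value = NA_real_),
                per_combination = empty_df(per_cols)))
  }
  # expand calls to (line, screened drug) via the drug map
  calls <- merge(calls, drug_map, by.x = "chosen_drug", by.y = "kb_drug")
  joined <- merge(calls, screen,
                  by.x = c("sample_id", "drug_id"),
                  by.y = c("cell_line_id", "drug_id"))
  pooled <- joined$ln_ic50
  global <- if (length(pooled) > 0L) {
    wt <- stats::wilcox.test(pooled, background, alternative = "two.sided",
                             exact = length(pooled) <= 8 &&
                               length(background) <= 8)
    list(n = length(pooled), statistic = unname(wt$statistic),
         p_value = wt$p.value)
  } else list(n = 0L, statistic = NA_real_, p_value = NA_real_)
  per <- list()
  sens <- joined[joined$effect == "sensitive", , drop = FALSE]
  combos <- unique(sens[, c("variant_key", "drug_id")])
  for (i in seq_len(nrow(combos))) {
    sub <- sens[sens$variant_key == combos$variant_key[i] &
                  sens$drug_id == combos$drug_id[i], , drop = FALSE]
    if (nrow(sub) < min_lines) next
    bg <- screen$ln_ic50[screen$drug_id == combos$drug_id[i]]
    wt <- stats::wilcox.test(sub$ln_ic50, bg, alternative = "two.sided",
                             exact = nrow(sub) <= 8 && length(bg) <= 8)
    per[[length(per) + 1L]] <- data.frame(
      variant_key = combos$variant_key[i], drug_id = combos$drug_id[i],
      n = nrow(sub), statistic = unname(wt$statistic),
      p_value = wt$p.value, stringsAsFactors = FALSE)
  }
  per_combination <- if (length(per) > 0L) do.call(rbind, per) else
    empty_df(per_cols)
  list(global = global, per_combination = per_combination)
}

#' Per-probe outlier-score regressions against LN(IC50)
#'
#' For each probe of a knowledgebase expression-sensitivity gene and each
#' mapped drug, ordinary least squares of LN(IC50) on the probe's outlier
#' score across cell lines (the cell-line panel itself is the reference
#' cohort for the score). Combinations need at least `min_lines` lines and
#' non-degenerate scores. A gene is validated iff at least one of its
#' probes is significant (p < 0.05 and slope B < 0).
#'
#' @param screen Screen table.
#' @param cl_expr Probe-by-cell-line expression matrix (probe ids as row
#'   names).
#' @param probe_map data.frame with columns probe_id, gene.
#' @param kb Resolved knowledgebase.
#' @param drug_map Mapping from [map_drugs()]`$map`.
#' @param min_lines Minimum lines per combination (default 5).
#' @return List with `regressions` (probe_id, gene, drug_id, slope,
#'   intercept, p_value, n, significant) and `validated_genes`.
#' @export
expression_sensitivity_regression <- function(screen, cl_expr, probe_map,
                                              kb, drug_map,
                                              min_lines = 5L) {
  feats <- kb_expression_features(kb)
  sens_genes <- feats$feature[feats$direction == "high"]
  kb_sens <- kb[kb$variant_class == "expression_high" &
                  kb$effect == "sensitive", , drop = FALSE]
  rows <- list()
  for (g in intersect(sens_genes, unique(probe_map$gene))) {
    probes <- probe_map$probe_id[probe_map$gene == g]
    probes <- intersect(probes, rownames(cl_expr))
    drugs_g <- unique(kb_sens$drug[kb_sens$gene == g])
    drug_ids <- unique(drug_map$drug_id[drug_map$kb_drug %in% drugs_g])
    for (p in probes) {
      v <- cl_expr[p, ]
      if (sum(!is.na(v)) < 4L) next
      qs <- cohort_quartiles(v)
      if (qs$iqr <= 0) next
      score <- outlier_score(v, qs$q1, qs$q3, qs$iqr, "high")
      names(score) <- colnames(cl_expr)
      for (d in drug_ids) {
        sub <- screen[screen$drug_id == d &
                        screen$cell_line_id %in% names(score), ,
                      drop = FALSE]
        x <- score[sub$cell_line_id]
        y <- sub$ln_ic50
        ok <- !is.na(x) & !is.na(y)
        x <- x[ok]; y <- y[ok]
        if (length(x) < min_lines) next
        if (stats::var(x) == 0) next  # degenerate predictor
        fit <- stats::lm(y ~ x)
        sm <- summary(fit)$coefficients
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = p, gene = g, drug_id = d,
          slope = unname(sm["x", "Estimate"]),
          intercept = unname(sm["(Intercept)", "Estimate"]),
          p_value = unname(sm["x", "Pr(>|t|)"]),
          n = length(x), stringsAsFactors = FALSE)
      }
    }
  }
  regressions <- if (length(rows) > 0L) do.call(rbind, rows) else
    empty_df(c("probe_id", "gene", "drug_id", "slope", "intercept",
               "p_value", "n"))
  regressions$significant <- regressions$p_value < 0.05 &
    regressions$slope < 0
  validated <- sort(unique(regressions$gene[regressions$significant]))
  list(regressions = regressions, validated_genes = validated)
}
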