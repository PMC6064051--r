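# Synthetic cohort generator. Emulates every input the pipeline consumes —
# knowledgebase TSV, MAF-dialect mutations, expression matrices, traits,
# residue-distance structures, and a cell-line screen — with planted effects
# recorded in ground-truth tables: druggable mutations at set frequencies,
# expression values shifted by k*IQR beyond the Tukey fence, spatial
# mutation hotspots inside a small ball, LN(IC50) shifts for sensitive
# biomarkers, and linear outlier-score/response slopes. All draws are fixed
# by the config seed.

#' Built-in synthetic knowledgebase
#'
#' A small variant/drug knowledgebase exercising every matching route:
#' exact missense, ambiguous single-residue, codon-range in-frame deletion,
#' multi-tumor-type entries with distinct evidence tiers, a resistant
#' entry, and expression-sensitivity entries.
#'
#' @return Knowledgebase data.frame (canonical columns plus entry_id).
#' @export
synthetic_kb <- function() {
  e <- function(gene, vc, spec, tt, eff, lvl, drug, cls)
    data.frame(gene = gene, variant_class = vc, variant_spec = spec,
               tumor_type = tt, effect = eff, evidence_level = lvl,
               drug = drug, drug_classes = cls, pubmed_id = "synthetic",
               stringsAsFactors = FALSE)
  kb <- rbind(
    e("BRAF", "missense_exact", "V600E", "SKCM", "sensitive",
      "fda_approved", "dabrafenib", "B-Raf inhibitor"),
    e("BRAF", "missense_exact", "V600E", "THCA", "sensitive",
      "clinical_trial", "vemurafenib", "B-Raf inhibitor"),
    e("BRAF", "missense_position", "V600", "SKCM", "sensitive",
      "clinical_trial", "trametinib", "MEK inhibitor"),
    e("EGFR", "aa_range", "729-761:inframe_del", "LUAD", "sensitive",
      "fda_approved", "erlotinib", "EGFR inhibitor"),
    e("NRAS", "missense_position", "Q61", "SKCM", "sensitive",
      "case_report", "binimetinib", "MEK inhibitor"),
    e("KRAS", "missense_position", "G12", "COADREAD", "sensitive",
      "preclinical", "selumetinib", "MEK inhibitor"),
    e("PIK3CA", "missense_exact", "E545K", "COADREAD", "sensitive",
      "clinical_trial", "alpelisib", "PI3K inhibitor"),
    e("RAC1", "missense_exact", "P29S", "SKCM", "resistant",
      "preclinical", "dabrafenib", "B-Raf inhibitor"),
    e("ERBB2", "expression_high", "", "BRCA", "sensitive",
      "fda_approved", "trastuzumab", "HER2 inhibitor"),
    e("ESR1", "expression_high", "", "BRCA", "sensitive",
      "fda_approved", "tamoxifen", "Hormone therapy"),
    e("MDM2", "expression_high", "", "UNSPECIFIED", "sensitive",
      "preclinical", "nutlin-3a", "MDM2 inhibitor"),
    e("EGFR", "expression_high", "", "LUAD", "sensitive",
      "clinical_trial", "erlotinib", "EGFR inhibitor"),
    e("AR", "expression_high", "", "PRAD", "sensitive",
      "fda_approved", "enzalutamide", "Hormone therapy"),
    e("DLL3", "expression_high", "", "UNSPECIFIED", "sensitive",
      "clinical_trial", "rovalpituzumab", "Antibody-drug conjugate"),
    e("CDK6", "expression_high", "", "BRCA", "sensitive",
      "clinical_trial", "palbociclib", "CDK inhibitor"),
    e("KIT", "expression_high", "", "UNSPECIFIED", "sensitive",
      "fda_approved", "imatinib", "KIT inhibitor"),
    e("PGR", "expression_high", "", "BRCA", "sensitive",
      "fda_approved", "tamoxifen", "Hormone therapy"),
    e("TP53", "frameshift", "*", "UNSPECIFIED", "sensitive",
      "preclinical", "azd1775", "WEE1 inhibitor")
  )
  kb$entry_id <- seq_len(nrow(kb))
  kb
}

# Ten visualization drug classes of the synthetic knowledgebase
#' @rdname synthetic_kb
#' @export
synthetic_viz_classes <- function() {
  c("B-Raf inhibitor", "MEK inhibitor", "EGFR inhibitor", "PI3K inhibitor",
    "HER2 inhibitor", "Hormone therapy", "MDM2 inhibitor", "CDK inhibitor",
    "KIT inhibitor", "WEE1 inhibitor")
}

#' Simulation configuration with study-condition defaults
#'
#' Defaults encode the study conditions the generator emulates: an exact
#' missense driver at 40% of synthetic melanoma samples, a codon-range
#' in-frame deletion at 10% of lung adenocarcinoma, outlier shifts of 3 IQR
#' (comfortably beyond the 1.5 fence), hotspot residues inside a 4 A ball
#' with decoys at 15 A or more, a -2 LN(IC50) shift for mutant lines and a
#' -0.8 outlier-score/response slope with noise 0.1.
#'
#' @param seed Integer seed fixing every draw.
#' @param ... Named overrides of any default field.
#' @return A list of class "sim_config".
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_samples = c(SKCM = 120L, THCA = 100L, LUAD = 120L, COADREAD = 120L,
                  BRCA = 140L, GBM = 100L),
    kb = synthetic_kb(),
    mutation_freqs = data.frame(
      cancer_type = c("SKCM", "THCA", "SKCM", "LUAD", "COADREAD",
                      "COADREAD", "SKCM", "GBM", "SKCM", "SKCM", "SKCM"),
      gene = c("BRAF", "BRAF", "NRAS", "EGFR", "KRAS", "PIK3CA", "RAC1",
               "TP53", "BRAF", "BRAF", "BRAF"),
      protein_change = c("V600E", "V600E", "Q61K", "E746_A750del", "G12D",
                         "E545K", "P29S", "R213Tfs*5", "G596D", "K601E",
                         "W604L"),
      mutation_class = c("missense", "missense", "missense", "inframe_del",
                         "missense", "missense", "missense", "frameshift",
                         "missense", "missense", "missense"),
      indel_length = c(0L, 0L, 0L, 15L, 0L, 0L, 0L, 1L, 0L, 0L, 0L),
      freq = c(0.40, 0.25, 0.12, 0.10, 0.20, 0.05, 0.05, 0.10, 0.03, 0.03,
               0.02),
      # kb_druggable marks variants a knowledgebase entry matches; the
      # BRAF V600-neighborhood missenses are uncatalogued (putative via
      # spatial clustering), RAC1 P29S matches a resistant entry
      kb_druggable = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                       FALSE, FALSE, FALSE),
      effect = c("sensitive", "sensitive", "sensitive", "sensitive",
                 "sensitive", "sensitive", "resistant", "sensitive",
                 NA, NA, NA),
      stringsAsFactors = FALSE),
    passenger_genes = c("TTN", "MUC16", "OBSCN", "USH2A", "SYNE1", "FLG"),
    passenger_lambda = 6,
    common_variant_rate = 0.05,
    n_duplicate_pairs = 2L,
    duplicate_concordance = 0.7,
    n_small_pairs = 1L,
    n_large_indels = 3L,
    n_boundary_indels = 2L,
    expression = list(
      extra_genes = c("GAPDH", "ACTB", "RPL13A"),
      phosphosites = c("EGFR:pY1068", "ESR1:pS118"),
      mean_range = c(6, 10), sd = 1,
      mrna_coverage = 0.9, protein_coverage = 0.7,
      protein_missing_rate = 0.1,
      n_outliers = 5L, shift_iqr = 3),
    structure = list(structure_id = "SYN1", gene = "BRAF",
                     residues = 581:620,
                     hotspot_residues = list(c(596L, 600L, 601L, 604L,
                                               613L)),
                     ball_radius = 4, decoy_spacing = 15),
    screen = list(n_lines = 120L, bg_mean = 2.5, bg_sd = 1.2,
                  delta = 2, beta = -0.8, sigma = 0.1,
                  mutation_freq = 0.15),
    traits = list(sex_probs = c(MALE = 0.5, FEMALE = 0.5),
                  race_probs = c(WHITE = 0.6, BLACK = 0.2, ASIAN = 0.2))
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "sim_config")
}

# Internal: random missense protein change avoiding a residue set
random_missense <- function(n, max_pos = 1200L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste0(sample(aa, n, replace = TRUE),
         sample(seq_len(max_pos), n, replace = TRUE),
         sample(aa, n, replace = TRUE))
}

#' Simulate a tumor cohort with ground truth
#'
#' Generates the knowledgebase, MAF, mRNA and protein expression matrices,
#' and traits in the exact dialects the reader functions consume, with
#' truth tables listing every planted druggable sample, outlier cell,
#' duplicate pair, and common variant.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory: when given, all tables are written as
#'   TSV files there.
#' @return List: kb, maf, mrna, protein, traits, truth (a list of truth
#'   tables), and file paths when `out_dir` was used.
#' @export
simulate_cohort <- function(config = sim_config(), out_dir = NULL) {
  set.seed(config$seed)
  samples <- unlist(lapply(names(config$n_samples), function(ct)
    sprintf("%s-%04d", ct, seq_len(config$n_samples[[ct]]))))
  cancer_type <- rep(names(config$n_samples), config$n_samples)
  names(cancer_type) <- samples

  maf_rows <- list()
  truth_druggable <- list()
  add_row <- function(sid, gene, pc, class, ilen = 0L, af = NA_real_,
                      path = FALSE) {
    data.frame(Tumor_Sample_Barcode = sid, Hugo_Symbol = gene,
               Variant_Classification = switch(class,
                 missense = "Missense_Mutation",
                 nonsense = "Nonsense_Mutation",
                 frameshift = "Frame_Shift_Del",
                 inframe_del = "In_Frame_Del",
                 inframe_ins = "In_Frame_Ins", "Other"),
               HGVSp_Short = paste0("p.", pc), Indel_Length = ilen,
               Population_AF = af, Pathogenic_Flag = path,
               Cancer_Type = cancer_type[sid], stringsAsFactors = FALSE)
  }
  # planted driver mutations at configured frequencies
  for (i in seq_len(nrow(config$mutation_freqs))) {
    f <- config$mutation_freqs[i, ]
    pool <- samples[cancer_type == f$cancer_type]
    hit <- pool[stats::runif(length(pool)) < f$freq]
    for (s in hit) {
      maf_rows[[length(maf_rows) + 1L]] <-
        add_row(s, f$gene, f$protein_change, f$mutation_class,
                f$indel_length, path = TRUE)
      if (isTRUE(f$kb_druggable))
        truth_druggable[[length(truth_druggable) + 1L]] <- data.frame(
          sample_id = s, cancer_type = f$cancer_type, gene = f$gene,
          protein_change = f$protein_change, effect = f$effect,
          stringsAsFactors = FALSE)
    }
  }
  # passenger mutations; a configured fraction are common non-pathogenic
  truth_common <- list()
  for (s in samples) {
    k <- stats::rpois(1, config$passenger_lambda)
    if (k == 0L) next
    genes <- sample(config$passenger_genes, k, replace = TRUE)
    pcs <- random_missense(k)
    common <- stats::runif(k) < config$common_variant_rate
    for (j in seq_len(k)) {
      af <- if (common[j]) 0.001 else NA_real_
      maf_rows[[length(maf_rows) + 1L]] <-
        add_row(s, genes[j], pcs[j], "missense", af = af)
      if (common[j])
        truth_common[[length(truth_common) + 1L]] <- data.frame(
          sample_id = s, gene = genes[j], protein_change = pcs[j],
          stringsAsFactors = FALSE)
    }
  }
  # large (>100 bp, must be removed) and boundary (100 bp, kept) indels
  truth_large <- list()
  for (j in seq_len(config$n_large_indels)) {
    s <- sample(samples, 1)
    pc <- paste0("K", 100 + j, "del")
    maf_rows[[length(maf_rows) + 1L]] <-
      add_row(s, "ARID1A", pc, "inframe_del", ilen = 150L)
    truth_large[[length(truth_large) + 1L]] <- data.frame(
      sample_id = s, gene = "ARID1A", protein_change = pc,
      indel_length = 150L, stringsAsFactors = FALSE)
  }
  for (j in seq_len(config$n_boundary_indels)) {
    s <- sample(samples, 1)
    maf_rows[[length(maf_rows) + 1L]] <-
      add_row(s, "ARID1B", paste0("K", 200 + j, "del"), "inframe_del",
              ilen = 100L)
  }
  maf <- do.call(rbind, maf_rows)

  # near-duplicate samples: copy a share of an existing sample's variants
  truth_dup <- list()
  per_sample <- split(seq_len(nrow(maf)), maf$Tumor_Sample_Barcode)
  big <- names(per_sample)[vapply(per_sample, length, integer(1)) >= 8L]
  dup_sources <- sample(big, min(config$n_duplicate_pairs, length(big)))
  for (d in seq_along(dup_sources)) {
    src <- dup_sources[d]
    idx <- per_sample[[src]]
    n_src <- length(idx)
    n_shared <- ceiling(config$duplicate_concordance * n_src)
    new_id <- sprintf("DUP-%04d", d)
    shared <- maf[sample(idx, n_shared), , drop = FALSE]
    shared$Tumor_Sample_Barcode <- new_id
    novel_n <- n_src - n_shared
    novel <- do.call(rbind, lapply(seq_len(max(novel_n, 0L)), function(j)
      add_row(src, sample(config$passenger_genes, 1), random_missense(1),
              "missense")))
    if (!is.null(novel)) novel$Tumor_Sample_Barcode <- new_id
    cancer_type[new_id] <- cancer_type[src]
    maf <- rbind(maf, shared, novel)
    truth_dup[[length(truth_dup) + 1L]] <- data.frame(
      sample_a = src, sample_b = new_id,
      concordance = n_shared / n_src, stringsAsFactors = FALSE)
  }
  # small identical pairs (<= 5 variants each; both must survive QC)
  truth_small <- list()
  for (d in seq_len(config$n_small_pairs)) {
    ids <- sprintf("SML-%04d-%s", d, c("A", "B"))
    pcs <- random_missense(3)
    genes <- sample(config$passenger_genes, 3, replace = TRUE)
    for (id in ids) {
      cancer_type[id] <- "GBM"
      for (j in 1:3)
        maf <- rbind(maf, add_row(id, genes[j], pcs[j], "missense"))
    }
    truth_small[[length(truth_small) + 1L]] <- data.frame(
      sample_a = ids[1], sample_b = ids[2], stringsAsFactors = FALSE)
  }
  rownames(maf) <- NULL
  all_samples <- names(cancer_type)

  # traits
  tcfg <- config$traits
  traits <- data.frame(
    sample_id = all_samples,
    cancer_type = unname(cancer_type),
    sex = sample(names(tcfg$sex_probs), length(all_samples), replace = TRUE,
                 prob = tcfg$sex_probs),
    race = sample(names(tcfg$race_probs), length(all_samples),
                  replace = TRUE, prob = tcfg$race_probs),
    stringsAsFactors = FALSE)

  # expression matrices with planted outliers
  ecfg <- config$expression
  kb_genes <- unique(config$kb$gene[config$kb$variant_class %in%
                                      c("expression_high",
                                        "expression_low")])
  make_matrix <- function(features, cov_frac, missing_rate, level) {
    cols <- sort(sample(samples, round(cov_frac * length(samples))))
    m <- matrix(NA_real_, nrow = length(features), ncol = length(cols),
                dimnames = list(features, cols))
    for (f in features) {
      mu <- stats::runif(1, ecfg$mean_range[1], ecfg$mean_range[2])
      m[f, ] <- stats::rnorm(length(cols), mu, ecfg$sd)
    }
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(m)) < missing_rate, nrow = nrow(m))
      m[mask] <- NA_real_
    }
    attr(m, "level") <- level
    m
  }
  plant_outliers <- function(m, features, level) {
    truth <- list()
    for (f in features) {
      v <- m[f, ]
      ok <- which(!is.na(v))
      if (length(ok) < 4L) next
      q <- stats::quantile(v[ok], c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2] - q[1]
      pick <- sample(ok, min(ecfg$n_outliers, length(ok)))
      if (length(pick) == 0L) next
      m[f, pick] <- q[2] + ecfg$shift_iqr * iqr
      truth[[length(truth) + 1L]] <- data.frame(
        level = level, feature = f, sample_id = colnames(m)[pick],
        shift_iqr = ecfg$shift_iqr, stringsAsFactors = FALSE)
    }
    list(m = m, truth = if (length(truth) > 0L) do.call(rbind, truth)
         else NULL)
  }
  mrna_feats <- c(kb_genes, ecfg$extra_genes)
  mrna <- make_matrix(mrna_feats, ecfg$mrna_coverage, 0, "mrna")
  pm <- plant_outliers(mrna, kb_genes, "mrna")
  mrna <- pm$m
  attr(mrna, "level") <- "mrna"
  truth_outliers <- pm$truth
  prot_feats <- c(kb_genes, ecfg$phosphosites)
  protein <- make_matrix(prot_feats, ecfg$protein_coverage,
                         ecfg$protein_missing_rate, "protein")
  pp <- plant_outliers(protein, prot_feats, "protein")
  protein <- pp$m
  attr(protein, "level") <- "protein"
  truth_outliers <- rbind(truth_outliers, pp$truth)

  out <- list(
    kb = config$kb, maf = maf, mrna = mrna, protein = protein,
    traits = traits,
    truth = list(
      druggable = if (length(truth_druggable) > 0L)
        do.call(rbind, truth_druggable) else NULL,
      outliers = truth_outliers,
      duplicates = if (length(truth_dup) > 0L)
        do.call(rbind, truth_dup) else NULL,
      small_pairs = if (length(truth_small) > 0L)
        do.call(rbind, truth_small) else NULL,
      common_variants = if (length(truth_common) > 0L)
        do.call(rbind, truth_common) else NULL,
      large_indels = if (length(truth_large) > 0L)
        do.call(rbind, truth_large) else NULL))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_knowledgebase(out$kb, file.path(out_dir, "knowledgebase.tsv"))
    write_tsv_file(out$maf, file.path(out_dir, "mutations.maf.tsv"))
    write_tsv_file(data.frame(feature = rownames(mrna), mrna,
                              check.names = FALSE),
                   file.path(out_dir, "expression_mrna.tsv"))
    write_tsv_file(data.frame(feature = rownames(protein), protein,
                              check.names = FALSE),
                   file.path(out_dir, "expression_protein.tsv"))
    write_tsv_file(traits, file.path(out_dir, "traits.tsv"))
    out$paths <- file.path(out_dir, c("knowledgebase.tsv",
                                      "mutations.maf.tsv",
                                      "expression_mrna.tsv",
                                      "expression_protein.tsv",
                                      "traits.tsv"))
  }
  out
}

#' Simulate a protein structure as a residue-distance table
#'
#' Hotspot residues are placed inside a ball of the configured radius
#' (pairwise distances at most `ball_radius`); decoy residues sit on a line
#' with at least `decoy_spacing` between any two decoys and far from every
#' hotspot.
#'
#' @param config A [sim_config()] (fields under `structure`).
#' @return List: `distances` (structure_id, gene, res_i, res_j,
#'   distance_A) and `truth` with the hotspot residue sets.
#' @export
simulate_structure <- function(config = sim_config()) {
  set.seed(config$seed + 1L)
  s <- config$structure
  residues <- as.integer(s$residues)
  hotspots <- lapply(s$hotspot_residues, as.integer)
  hot_all <- unlist(hotspots)
  if (anyDuplicated(hot_all) || !all(hot_all %in% residues))
    stop("hotspot larger than structure or residues outside it",
         call. = FALSE)
  coords <- matrix(NA_real_, nrow = length(residues), ncol = 3,
                   dimnames = list(as.character(residues), NULL))
  for (h in seq_along(hotspots)) {
    center <- c((h - 1) * 200, 0, 0)
    for (r in hotspots[[h]]) {
      # uniform in a ball of radius ball_radius/2 => pairwise <= ball_radius
      repeat {
        p <- stats::runif(3, -s$ball_radius / 2, s$ball_radius / 2)
        if (sqrt(sum(p^2)) <= s$ball_radius / 2) break
      }
      coords[as.character(r), ] <- center + p
    }
  }
  decoys <- setdiff(residues, hot_all)
  for (j in seq_along(decoys))
    coords[as.character(decoys[j]), ] <- c(5000 + j * s$decoy_spacing, 0, 0)
  pr <- t(utils::combn(length(residues), 2L))
  d <- sqrt(rowSums((coords[pr[, 1], , drop = FALSE] -
                       coords[pr[, 2], , drop = FALSE])^2))
  distances <- data.frame(structure_id = s$structure_id, gene = s$gene,
                          res_i = residues[pr[, 1]],
                          res_j = residues[pr[, 2]], distance_A = d,
                          stringsAsFactors = FALSE)
  list(distances = distances, truth = list(hotspots = hotspots))
}

#' Simulate a cell-line drug screen with planted effects
#'
#' Lines carrying a sensitive knowledgebase mutation have their LN(IC50)
#' for the paired drug shifted down by `delta`; for expression-linked drugs
#' the response is a linear function of the outlier score with slope
#' `beta` and noise `sigma`.
#'
#' @param config A [sim_config()] (fields under `screen`).
#' @param kb Knowledgebase (defaults to the config's).
#' @return List: screen, cl_maf (cell-line mutations), cl_expr (probe x
#'   line matrix), probe_map, screen_drugs, drug_map, and truth (delta and
#'   beta per planted effect).
#' @export
simulate_screen <- function(config = sim_config(), kb = config$kb) {
  set.seed(config$seed + 2L)
  scfg <- config$screen
  tissues <- names(config$n_samples)
  lines <- sprintf("CL-%04d", seq_len(scfg$n_lines))
  tissue <- sample(tissues, scfg$n_lines, replace = TRUE)
  names(tissue) <- lines

  # screened-compound table: one compound per knowledgebase drug
  kb_drugs <- sort(unique(kb$drug))
  screen_drugs <- data.frame(
    drug_id = sprintf("D%03d", seq_along(kb_drugs)),
    drug_name = kb_drugs,
    synonyms = toupper(kb_drugs),
    targets = vapply(kb_drugs, function(d)
      paste(sort(unique(kb$gene[kb$drug == d])), collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE)
  drug_map <- map_drugs(kb_drugs, screen_drugs)$map

  # cell-line mutations: exact sensitive missense entries planted uniformly
  exact <- kb[kb$variant_class == "missense_exact" &
                kb$effect == "sensitive", , drop = FALSE]
  exact <- exact[!duplicated(paste(exact$gene, exact$variant_spec)), ,
                 drop = FALSE]
  cl_rows <- list()
  carrier <- list()  # variant_key -> line ids
  for (i in seq_len(nrow(exact))) {
    hit <- lines[stats::runif(scfg$n_lines) < scfg$mutation_freq]
    vk <- paste(exact$gene[i], exact$variant_spec[i], sep = ":")
    carrier[[vk]] <- hit
    for (l in hit) {
      cl_rows[[length(cl_rows) + 1L]] <- data.frame(
        Tumor_Sample_Barcode = l, Hugo_Symbol = exact$gene[i],
        Variant_Classification = "Missense_Mutation",
        HGVSp_Short = paste0("p.", exact$variant_spec[i]),
        Indel_Length = 0L, Population_AF = NA_real_,
        Pathogenic_Flag = TRUE, Cancer_Type = tissue[l],
        stringsAsFactors = FALSE)
    }
  }
  cl_maf_raw <- do.call(rbind, cl_rows)
  cl_maf <- data.frame(
    sample_id = cl_maf_raw$Tumor_Sample_Barcode,
    cancer_type = cl_maf_raw$Cancer_Type,
    gene = cl_maf_raw$Hugo_Symbol,
    protein_change = sub("^p\\.", "", cl_maf_raw$HGVSp_Short),
    mutation_class = "missense", indel_length = 0L,
    population_af = NA_real_, pathogenic_flag = TRUE,
    stringsAsFactors = FALSE)

  # expression probes for expression-sensitivity genes (2 probes per gene)
  expr_genes <- unique(kb$gene[kb$variant_class == "expression_high" &
                                 kb$effect == "sensitive"])
  probe_map <- do.call(rbind, lapply(expr_genes, function(g)
    data.frame(probe_id = paste0("P_", g, "_", 1:2), gene = g,
               stringsAsFactors = FALSE)))
  cl_expr <- matrix(NA_real_, nrow = nrow(probe_map), ncol = length(lines),
                    dimnames = list(probe_map$probe_id, lines))
  for (g in expr_genes) {
    base <- stats::rnorm(length(lines), 8, 1)
    cl_expr[paste0("P_", g, "_1"), ] <- base
    cl_expr[paste0("P_", g, "_2"), ] <- base +
      stats::rnorm(length(lines), 0, 0.2)
  }

  # mutation-paired drugs: drug of the mutation's max-evidence entry
  truth_delta <- list()
  shift_for <- list()  # drug_id -> carrier lines
  for (vk in names(carrier)) {
    parts <- strsplit(vk, ":", fixed = TRUE)[[1]]
    sub <- kb[kb$gene == parts[1] & kb$variant_spec == parts[2] &
                kb$effect == "sensitive", , drop = FALSE]
    drug <- sub$drug[which.max(evidence_rank(sub$evidence_level))]
    dids <- drug_map$drug_id[drug_map$kb_drug == drug]
    for (did in dids) {
      shift_for[[did]] <- union(shift_for[[did]], carrier[[vk]])
      truth_delta[[length(truth_delta) + 1L]] <- data.frame(
        variant_key = vk, drug_id = did, delta = scfg$delta,
        stringsAsFactors = FALSE)
    }
  }
  # expression-paired drugs: pure linear score-response (first probe causal)
  expr_drug_of <- list()
  kb_expr <- kb[kb$variant_class == "expression_high" &
                  kb$effect == "sensitive", , drop = FALSE]
  truth_beta <- list()
  for (g in expr_genes) {
    sub <- kb_expr[kb_expr$gene == g, , drop = FALSE]
    drug <- sub$drug[which.max(evidence_rank(sub$evidence_level))]
    dids <- drug_map$drug_id[drug_map$kb_drug == drug]
    for (did in dids) {
      # keep planted effects disjoint: one causal gene per drug, and no
      # drug with both a mutation shift and an expression slope
      if (did %in% names(shift_for) || did %in% names(expr_drug_of)) next
      expr_drug_of[[did]] <- g
      truth_beta[[length(truth_beta) + 1L]] <- data.frame(
        gene = g, drug_id = did, beta = scfg$beta, sigma = scfg$sigma,
        stringsAsFactors = FALSE)
    }
  }

  rows <- list()
  for (did in screen_drugs$drug_id) {
    y <- stats::rnorm(length(lines), scfg$bg_mean, scfg$bg_sd)
    if (did %in% names(expr_drug_of)) {
      g <- expr_drug_of[[did]]
      v <- cl_expr[paste0("P_", g, "_1"), ]
      q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
      score <- (v - q[2]) / (q[2] - q[1])
      y <- scfg$bg_mean + scfg$beta * score +
        stats::rnorm(length(lines), 0, scfg$sigma)
    }
    if (did %in% names(shift_for))
      y[lines %in% shift_for[[did]]] <-
        y[lines %in% shift_for[[did]]] - scfg$delta
    rows[[length(rows) + 1L]] <- data.frame(
      cell_line_id = lines, tissue_type = unname(tissue[lines]),
      drug_id = did, ln_ic50 = y, stringsAsFactors = FALSE)
  }
  screen <- do.call(rbind, rows)
  rownames(screen) <- NULL
  list(screen = screen, cl_maf = cl_maf, cl_expr = cl_expr,
       probe_map = probe_map, screen_drugs = screen_drugs,
       drug_map = drug_map,
       truth = list(delta = if (length(truth_delta) > 0L)
         do.call(rbind, truth_delta) else NULL,
         beta = if (length(truth_beta) > 0L)
           do.call(rbind, truth_beta) else NULL))
}

#' Simulate a two-arm cohort with planted demographic enrichment
#'
#' One cancer type, two demographic categories of `n_per_arm` tumors each;
#' the druggable-gene carrier probability in arm A is raised to the planted
#' odds ratio against the baseline `p_b` in arm B.
#'
#' @param n_per_arm Tumors per category (default 200).
#' @param p_b Baseline carrier probability (default 0.10).
#' @param odds_ratio Planted odds ratio (default 4).
#' @param seed RNG seed.
#' @param trait "sex" or "race".
#' @return List: calls, traits, p_a, p_b.
#' @export
simulate_demographic_cohort <- function(n_per_arm = 200L, p_b = 0.10,
                                        odds_ratio = 4, seed = 1L,
                                        trait = "sex") {
  set.seed(seed)
  odds_b <- p_b / (1 - p_b)
  p_a <- odds_ratio * odds_b / (1 + odds_ratio * odds_b)
  cats <- if (trait == "sex") c("MALE", "FEMALE") else c("WHITE", "BLACK")
  ids <- sprintf("DEM-%04d", seq_len(2L * n_per_arm))
  arm <- rep(cats, each = n_per_arm)
  druggable <- c(stats::runif(n_per_arm) < p_a,
                 stats::runif(n_per_arm) < p_b)
  traits <- data.frame(sample_id = ids, cancer_type = "LUAD",
                       sex = if (trait == "sex") arm else "MALE",
                       race = if (trait == "race") arm else "WHITE",
                       stringsAsFactors = FALSE)
  hit <- ids[druggable]
  calls <- data.frame(
    sample_id = hit, cancer_type = "LUAD", gene = "EGFR",
    variant_key = "EGFR:L858R", data_level = "mutation",
    effect = "sensitive", specificity = "non_specific",
    chosen_drug = "erlotinib", chosen_evidence = "fda_approved",
    all_matches = "", stringsAsFactors = FALSE)
  list(calls = calls, traits = traits, p_a = p_a, p_b = p_b)
}
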