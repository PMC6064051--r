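# Multi-omics integration: unify mutation, expression-outlier and putative
# cluster calls per tumor, report tumors druggable on two or more data
# levels, break samples into drug-class sectors with cross-links, flag
# co-occurring alterations (combination candidates and resistance
# co-occurrence), and compute cumulative evidence-tier curves with the
# putative (hotspot3d) tier below preclinical.

# Internal: ordinal rank over the extended tier scale (putative lowest)
tier_rank <- function(tier) {
  scale <- c(hotspot3d = 1, preclinical = 2, case_report = 3,
             clinical_trial = 4, fda_approved = 5)
  r <- scale[tier]
  if (anyNA(r))
    stop("unknown tier(s): ", paste(unique(tier[is.na(r)]), collapse = ", "),
         call. = FALSE)
  unname(r)
}

# Internal: drug -> drug classes lookup from the knowledgebase table
drug_class_lookup <- function(kb) {
  classes <- split_drug_classes(kb$drug_classes)
  out <- list()
  for (i in seq_len(nrow(kb)))
    out[[kb$drug[i]]] <- sort(unique(c(out[[kb$drug[i]]], classes[[i]])))
  out
}

#' Turn expression-outlier calls into druggability calls
#'
#' Each outlier call is matched to the knowledgebase expression entries for
#' its parent gene and direction; effect, chosen drug, evidence and
#' cancer-type specificity are resolved with the same rules as for
#' mutations (sensitive over resistant, globally maximal evidence,
#' specificity on exact cancer-type match at the maximal level).
#'
#' @param outlier_calls Calls from [call_outliers()].
#' @param kb Resolved knowledgebase.
#' @param traits Traits data.frame mapping sample_id to cancer_type.
#' @return Druggability-call data.frame with data_level = the expression
#'   level of each call.
#' @export
annotate_outliers <- function(outlier_calls, kb, traits) {
  cols <- c("sample_id", "cancer_type", "gene", "variant_key", "data_level",
            "effect", "specificity", "chosen_drug", "chosen_evidence",
            "all_matches")
  if (nrow(outlier_calls) == 0L) return(empty_df(cols))
  gene_of <- sub(":.*$", "", outlier_calls$feature)
  ct <- traits$cancer_type[match(outlier_calls$sample_id, traits$sample_id)]
  out <- list()
  for (i in seq_len(nrow(outlier_calls))) {
    wanted <- if (outlier_calls$direction[i] == "high")
      "expression_high" else "expression_low"
    sub <- kb[kb$gene == gene_of[i] & kb$variant_class == wanted, ,
              drop = FALSE]
    if (nrow(sub) == 0L) next
    effect <- if (any(sub$effect == "sensitive")) "sensitive" else "resistant"
    sub <- sub[sub$effect == effect, , drop = FALSE]
    rank <- evidence_rank(sub$evidence_level)
    top <- sub[rank == max(rank), , drop = FALSE]
    specific <- !is.na(ct[i]) &&
      ct[i] %in% setdiff(unique(top$tumor_type), "UNSPECIFIED")
    out[[length(out) + 1L]] <- data.frame(
      sample_id = outlier_calls$sample_id[i],
      cancer_type = ct[i],
      gene = gene_of[i],
      variant_key = paste0(outlier_calls$feature[i], ":",
                           outlier_calls$direction[i]),
      data_level = outlier_calls$level[i],
      effect = effect,
      specificity = if (specific) "cancer_type_specific" else "non_specific",
      chosen_drug = sort(unique(top$drug))[1],
      chosen_evidence = top$evidence_level[1],
      all_matches = paste(sub$entry_id, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty_df(cols))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Internal: collapse a data_level to its integration level
integration_level <- function(data_level) {
  ifelse(data_level %in% c("protein", "phosphoprotein"), "protein",
         data_level)
}

#' Build per-tumor multi-omics druggability profiles
#'
#' @param calls Combined druggability calls across data levels (rbind of
#'   [annotate_cohort()], [annotate_outliers()], and
#'   [putative_druggability_calls()] outputs).
#' @param profiled Named list of sample-id vectors: which samples have
#'   mutation, mrna, and protein data.
#' @param traits Traits data.frame; samples with calls but absent from
#'   traits are kept with NA cancer type and a warning.
#' @param require_complete If TRUE (default) only samples profiled on all
#'   three levels enter the profile table (the multi-omics denominator).
#' @return data.frame with one row per sample: profiling flags, per-level
#'   druggable flags (sensitive calls only), the count of druggable core
#'   levels, and best evidence tiers in both specificity settings.
#' @export
build_profiles <- function(calls, profiled, traits,
                           require_complete = TRUE) {
  stopifnot(all(c("mutation", "mrna", "protein") %in% names(profiled)))
  samples <- if (require_complete) {
    Reduce(intersect, profiled[c("mutation", "mrna", "protein")])
  } else {
    Reduce(union, profiled[c("mutation", "mrna", "protein")])
  }
  samples <- sort(unique(samples))
  missing_traits <- setdiff(unique(calls$sample_id), traits$sample_id)
  if (length(missing_traits) > 0L)
    warning("sample(s) in calls but absent from traits: ",
            paste(missing_traits, collapse = ", "), call. = FALSE)
  sens <- calls[calls$effect == "sensitive", , drop = FALSE]
  sens$int_level <- integration_level(sens$data_level)
  level_flag <- function(s, lev)
    any(sens$sample_id == s & sens$int_level == lev)
  best_tier <- function(s, setting) {
    sub <- sens[sens$sample_id == s, , drop = FALSE]
    if (setting == "specific")
      sub <- sub[sub$specificity == "cancer_type_specific", , drop = FALSE]
    if (nrow(sub) == 0L) return(NA_character_)
    sub$chosen_evidence[which.max(tier_rank(sub$chosen_evidence))]
  }
  out <- data.frame(
    sample_id = samples,
    cancer_type = traits$cancer_type[match(samples, traits$sample_id)],
    profiled_mutation = samples %in% profiled$mutation,
    profiled_mrna = samples %in% profiled$mrna,
    profiled_protein = samples %in% profiled$protein,
    stringsAsFactors = FALSE)
  out$druggable_mutation <- vapply(samples, level_flag, logical(1),
                                   lev = "mutation")
  out$druggable_mrna <- vapply(samples, level_flag, logical(1), lev = "mrna")
  out$druggable_protein <- vapply(samples, level_flag, logical(1),
                                  lev = "protein")
  out$druggable_putative <- vapply(samples, level_flag, logical(1),
                                   lev = "cluster_putative")
  out$n_druggable_levels <- rowSums(out[, c("druggable_mutation",
                                            "druggable_mrna",
                                            "druggable_protein")])
  out$best_tier_specific <- vapply(samples, best_tier, character(1),
                                   setting = "specific")
  out$best_tier_nonspecific <- vapply(samples, best_tier, character(1),
                                      setting = "non_specific")
  rownames(out) <- NULL
  out
}

#' Fraction of tumors druggable on two or more data levels
#'
#' @param profiles Profile table from [build_profiles()].
#' @return List with `fraction`, `n_multiomics` and `n_total`.
#' @export
multiomics_fraction <- function(profiles) {
  if (nrow(profiles) == 0L)
    stop("no profiles: zero multi-omics denominator", call. = FALSE)
  n_multi <- sum(profiles$n_druggable_levels >= 2)
  list(fraction = n_multi / nrow(profiles), n_multiomics = n_multi,
       n_total = nrow(profiles))
}

#' Drug-class sector and link tables
#'
#' Assigns each sensitive call to the visualization drug classes of its
#' chosen drug; builds the per-class sector table, the cross-link table
#' (samples with biomarkers in two or more classes) and the within-class
#' multi-biomarker table (a sample with several biomarkers of the same data
#' level in one class).
#'
#' @param calls Combined druggability calls.
#' @param kb Knowledgebase (source of the drug -> class mapping).
#' @param viz_classes Character vector of exactly 10 visualization classes.
#' @return List of data.frames: `sectors`, `cross_links`, `within_links`.
#' @export
drug_class_sectors <- function(calls, kb, viz_classes) {
  stopifnot(length(viz_classes) == 10L)
  lookup <- drug_class_lookup(kb)
  sens <- calls[calls$effect == "sensitive" & !is.na(calls$chosen_drug), ,
                drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sens))) {
    cls <- intersect(lookup[[sens$chosen_drug[i]]], viz_classes)
    for (cl in cls) {
      rows[[length(rows) + 1L]] <- data.frame(
        drug_class = cl, sample_id = sens$sample_id[i],
        gene = sens$gene[i], data_level = sens$data_level[i],
        variant_key = sens$variant_key[i], stringsAsFactors = FALSE)
    }
  }
  sectors <- if (length(rows) > 0L) unique(do.call(rbind, rows)) else
    empty_df(c("drug_class", "sample_id", "gene", "data_level",
               "variant_key"))
  rownames(sectors) <- NULL
  # cross-links: unordered class pairs per sample
  cross <- list()
  for (s in unique(sectors$sample_id)) {
    cls <- sort(unique(sectors$drug_class[sectors$sample_id == s]))
    if (length(cls) >= 2L) {
      pr <- t(utils::combn(cls, 2L))
      cross[[length(cross) + 1L]] <- data.frame(
        sample_id = s, class_a = pr[, 1], class_b = pr[, 2],
        stringsAsFactors = FALSE)
    }
  }
  cross_links <- if (length(cross) > 0L) do.call(rbind, cross) else
    empty_df(c("sample_id", "class_a", "class_b"))
  # within-class links: >=2 biomarkers of the same data level in one class
  within <- list()
  key <- paste(sectors$sample_id, sectors$drug_class, sectors$data_level)
  for (k in unique(key)) {
    sub <- sectors[key == k, , drop = FALSE]
    if (length(unique(sub$variant_key)) >= 2L) {
      within[[length(within) + 1L]] <- data.frame(
        sample_id = sub$sample_id[1], drug_class = sub$drug_class[1],
        data_level = sub$data_level[1],
        biomarkers = paste(sort(unique(sub$variant_key)), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  within_links <- if (length(within) > 0L) do.call(rbind, within) else
    empty_df(c("sample_id", "drug_class", "data_level", "biomarkers"))
  list(sectors = sectors, cross_links = cross_links,
       within_links = within_links)
}

#' Co-occurring alteration pairs per tumor
#'
#' All unordered pairs of distinct alterations (across data levels) within a
#' sample. A sensitive+resistant pair is flagged as a potential
#' therapy-failure risk; a sensitive+sensitive pair whose chosen drugs map
#' to different class sets is flagged as a combination candidate.
#'
#' @param calls Combined druggability calls including resistant effects.
#' @param kb Knowledgebase for the drug -> class mapping.
#' @return data.frame: sample_id, key_a, key_b, effect_a, effect_b, flag.
#' @export
cooccurrence_report <- function(calls, kb) {
  cols <- c("sample_id", "key_a", "key_b", "effect_a", "effect_b", "flag")
  if (nrow(calls) == 0L) return(empty_df(cols))
  lookup <- drug_class_lookup(kb)
  out <- list()
  for (s in unique(calls$sample_id)) {
    sub <- calls[calls$sample_id == s, , drop = FALSE]
    sub <- sub[!duplicated(paste(sub$variant_key, sub$data_level)), ,
               drop = FALSE]
    if (nrow(sub) < 2L) next
    pr <- utils::combn(nrow(sub), 2L)
    for (j in seq_len(ncol(pr))) {
      a <- pr[1, j]; b <- pr[2, j]
      ea <- sub$effect[a]; eb <- sub$effect[b]
      cls_a <- lookup[[sub$chosen_drug[a]]]
      cls_b <- lookup[[sub$chosen_drug[b]]]
      flag <- if (xor(ea == "resistant", eb == "resistant")) {
        "sensitive_resistant"
      } else if (ea == "sensitive" && eb == "sensitive" &&
                 !setequal(cls_a, cls_b)) {
        "combination_candidate"
      } else "none"
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, key_a = sub$variant_key[a],
        key_b = sub$variant_key[b], effect_a = ea, effect_b = eb,
        flag = flag, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_df(cols))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cumulative evidence-tier curves across all data levels
#'
#' Cumulative fraction of cohort samples whose best sensitive call attains
#' at least each tier, walked from fda_approved down through preclinical to
#' the putative hotspot3d tier, in both specificity settings.
#'
#' @param calls Combined druggability calls (all levels, putative included).
#' @param cohort data.frame with the denominator samples (sample_id column).
#' @return data.frame: setting, tier, cumulative_fraction, n_samples.
#' @export
cumulative_tier_summary <- function(calls, cohort) {
  tiers <- c("fda_approved", "clinical_trial", "case_report", "preclinical",
             "hotspot3d")
  n <- length(unique(cohort$sample_id))
  sens <- calls[calls$effect == "sensitive" &
                  calls$sample_id %in% cohort$sample_id, , drop = FALSE]
  out <- list()
  for (setting in c("specific", "non_specific")) {
    sub <- if (setting == "specific") {
      sens[sens$specificity == "cancer_type_specific", , drop = FALSE]
    } else sens
    best <- if (nrow(sub) > 0L)
      tapply(tier_rank(sub$chosen_evidence), sub$sample_id, max)
    else numeric(0)
    for (tier in tiers) {
      out[[length(out) + 1L]] <- data.frame(
        setting = setting, tier = tier,
        cumulative_fraction = if (n > 0L)
          sum(best >= tier_rank(tier)) / n else 0,
        n_samples = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
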