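# Matching cohort mutations to the knowledgebase and resolving per-sample
# druggability calls. Matching follows three routes: (i) exact
# (gene, protein change) lookup, (ii) ambiguous single-residue lookup
# (reference amino acid + position, any substitution), and (iii) codon-range
# lookup for mutation classes restricted to a gene segment. Loose
# frameshift/nonsense categories match by (gene, class, position) with an
# optional wildcard position.

TIER_ORDER <- c("fda_approved", "clinical_trial", "case_report",
                "preclinical", "hotspot3d")

# Internal: build hash tables over the knowledgebase for fast lookup.
# exact:  gene\rspec            -> entry ids (missense_exact, inframe_indel_exact)
# posn:   gene\rREF POS         -> entry ids (missense_position)
# ranges: per-gene data.frame of range entries
# loose:  per-gene frameshift/nonsense entries
build_kb_index <- function(kb) {
  idx <- list(exact = new.env(parent = emptyenv()),
              posn = new.env(parent = emptyenv()),
              ranges = list(), loose = list())
  add <- function(env, key, id) {
    assign(key, c(if (exists(key, envir = env)) get(key, envir = env), id),
           envir = env)
  }
  for (i in seq_len(nrow(kb))) {
    vc <- kb$variant_class[i]
    g <- kb$gene[i]
    if (vc %in% c("missense_exact", "inframe_indel_exact")) {
      add(idx$exact, paste(g, kb$variant_spec[i], sep = "\r"), i)
    } else if (vc == "missense_position") {
      add(idx$posn, paste(g, kb$variant_spec[i], sep = "\r"), i)
    } else if (vc %in% c("aa_range", "inframe_indel_range")) {
      m <- regmatches(kb$variant_spec[i],
            regexec("^([0-9]+)-([0-9]+)(:([a-z_]+))?$", kb$variant_spec[i]))[[1]]
      row <- data.frame(id = i, start = as.integer(m[2]),
                        end = as.integer(m[3]),
                        class_restrict = if (nzchar(m[5])) m[5] else NA_character_,
                        range_kind = vc, stringsAsFactors = FALSE)
      idx$ranges[[g]] <- rbind(idx$ranges[[g]], row)
    } else if (vc %in% c("frameshift", "nonsense")) {
      spec <- kb$variant_spec[i]
      pos <- if (spec == "*") NA_integer_ else
        as.integer(sub("^[A-Z]?", "", spec))
      row <- data.frame(id = i, class = vc, pos = pos,
                        stringsAsFactors = FALSE)
      idx$loose[[g]] <- rbind(idx$loose[[g]], row)
    }
    # expression/cna/cnl/fusion entries never match mutation records
  }
  idx
}

# Internal: mutation classes a range entry accepts when no explicit
# restriction is given
RANGE_DEFAULT_CLASSES <- c("missense", "inframe_del", "inframe_ins")

#' Match one mutation record against the knowledgebase
#'
#' Returns the union of exact hits, ambiguous position hits (the reference
#' amino acid must agree: a V600 entry matches V600K but not A600K), range
#' hits (the mutation's class must match the range's class and its first
#' affected codon must fall within the range), and loose frameshift/nonsense
#' category hits.
#'
#' @param record One-row data.frame (or list) with gene, protein_change and
#'   mutation_class.
#' @param kb Resolved knowledgebase data.frame.
#' @param index Optional precomputed index from `build_kb_index(kb)`;
#'   supplying it avoids rebuilding per record.
#' @return Integer vector of matching kb row indices (possibly empty).
#' @export
match_mutation <- function(record, kb, index = NULL) {
  if (is.null(index)) index <- build_kb_index(kb)
  g <- record$gene
  pc <- parse_protein_change(record$protein_change)
  mclass <- record$mutation_class
  hits <- integer(0)
  getenv <- function(env, key) {
    if (exists(key, envir = env)) get(key, envir = env) else integer(0)
  }
  # (i) exact
  key <- paste(g, record$protein_change, sep = "\r")
  for (h in getenv(index$exact, key)) {
    vc <- kb$variant_class[h]
    if ((vc == "missense_exact" && mclass == "missense") ||
        (vc == "inframe_indel_exact" &&
           mclass %in% c("inframe_del", "inframe_ins")))
      hits <- c(hits, h)
  }
  # (ii) ambiguous position (missense only, reference aa must agree)
  if (mclass == "missense" && pc$ok) {
    key <- paste(g, paste0(pc$ref, pc$pos), sep = "\r")
    hits <- c(hits, getenv(index$posn, key))
  }
  # (iii) codon ranges, start codon inside [start, end]
  rng <- index$ranges[[g]]
  if (!is.null(rng) && pc$ok && !is.na(pc$pos)) {
    for (j in seq_len(nrow(rng))) {
      allowed <- if (!is.na(rng$class_restrict[j])) {
        rng$class_restrict[j]
      } else if (rng$range_kind[j] == "inframe_indel_range") {
        c("inframe_del", "inframe_ins")
      } else RANGE_DEFAULT_CLASSES
      if (mclass %in% allowed &&
          pc$pos >= rng$start[j] && pc$pos <= rng$end[j])
        hits <- c(hits, rng$id[j])
    }
  }
  # loose frameshift/nonsense categories
  loose <- index$loose[[g]]
  if (!is.null(loose) && mclass %in% c("frameshift", "nonsense")) {
    for (j in seq_len(nrow(loose))) {
      if (loose$class[j] != mclass) next
      if (is.na(loose$pos[j]) || (pc$ok && identical(pc$pos, loose$pos[j])))
        hits <- c(hits, loose$id[j])
    }
  }
  sort(unique(hits))
}

#' Resolve a druggability call from a mutation's knowledgebase matches
#'
#' If any sensitive match exists the call is sensitive (sensitive overrides
#' resistant); among effect-consistent matches the drug with the globally
#' maximal evidence level (any tumor type) is chosen, the alphabetically
#' first on an equal-evidence tie. The call is cancer-type specific iff the
#' sample's cancer type appears among the maximal-evidence matches
#' (UNSPECIFIED tumor types never confer specificity).
#'
#' @param record The mutation record (list or one-row data.frame).
#' @param matches Integer vector of kb row indices from [match_mutation()].
#' @param kb Knowledgebase data.frame.
#' @param sample_cancer_type The sample's cancer-type code.
#' @return One-row data.frame (a druggability call) or NULL if `matches`
#'   is empty.
#' @export
resolve_call <- function(record, matches, kb, sample_cancer_type) {
  if (length(matches) == 0L) return(NULL)
  sub <- kb[matches, , drop = FALSE]
  effect <- if (any(sub$effect == "sensitive")) "sensitive" else "resistant"
  sub <- sub[sub$effect == effect, , drop = FALSE]
  rank <- evidence_rank(sub$evidence_level)
  top <- sub[rank == max(rank), , drop = FALSE]
  chosen_drug <- sort(unique(top$drug))[1]
  specific <- sample_cancer_type %in%
    setdiff(unique(top$tumor_type), "UNSPECIFIED")
  data.frame(
    sample_id = record$sample_id,
    cancer_type = sample_cancer_type,
    gene = record$gene,
    variant_key = paste(record$gene, record$protein_change, sep = ":"),
    data_level = "mutation",
    effect = effect,
    specificity = if (specific) "cancer_type_specific" else "non_specific",
    chosen_drug = chosen_drug,
    chosen_evidence = top$evidence_level[1],
    all_matches = paste(sub$entry_id, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Annotate a whole cohort of mutations against the knowledgebase
#'
#' @param records QC'd mutation records.
#' @param kb Resolved knowledgebase.
#' @return data.frame of druggability calls (zero rows if nothing matches).
#' @export
annotate_cohort <- function(records, kb) {
  index <- build_kb_index(kb)
  calls <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    m <- match_mutation(rec, kb, index)
    if (length(m) > 0L)
      calls[[i]] <- resolve_call(rec, m, kb, rec$cancer_type)
  }
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (length(calls) == 0L) {
    return(empty_df(c("sample_id", "cancer_type", "gene", "variant_key",
                      "data_level", "effect", "specificity", "chosen_drug",
                      "chosen_evidence", "all_matches")))
  }
  do.call(rbind, calls)
}

#' Cumulative evidence-tier summary of mutation druggability
#'
#' For each cancer type and specificity setting, the cumulative fraction of
#' samples whose best sensitive call attains at least each evidence tier
#' (fda_approved first). Each sample counts once, at its best tier, so the
#' cumulative fractions nest. Only sensitive calls count toward
#' druggability; resistant calls are excluded here.
#'
#' @param calls Druggability calls from [annotate_cohort()].
#' @param cohort data.frame with sample_id and cancer_type for every sample
#'   in the denominator (traits table works).
#' @param tiers Evidence tiers in cumulative (best-first) order.
#' @return data.frame: cancer_type, setting, tier, n_samples,
#'   cumulative_fraction.
#' @export
summarize_mutation_druggability <- function(calls, cohort,
                                            tiers = c("fda_approved",
                                                      "clinical_trial",
                                                      "case_report",
                                                      "preclinical")) {
  if (nrow(cohort) == 0L)
    return(empty_df(c("cancer_type", "setting", "tier", "n_samples",
                      "cumulative_fraction")))
  calls <- calls[calls$effect == "sensitive", , drop = FALSE]
  out <- list()
  for (ct in sort(unique(cohort$cancer_type))) {
    samples <- unique(cohort$sample_id[cohort$cancer_type == ct])
    n <- length(samples)
    ct_calls <- calls[calls$sample_id %in% samples, , drop = FALSE]
    for (setting in c("specific", "non_specific")) {
      sub <- if (setting == "specific") {
        ct_calls[ct_calls$specificity == "cancer_type_specific", ,
                 drop = FALSE]
      } else ct_calls
      best <- tapply(evidence_rank(sub$chosen_evidence), sub$sample_id, max)
      for (ti in seq_along(tiers)) {
        thresh <- evidence_rank(tiers[ti])
        cum_n <- sum(best >= thresh)
        out[[length(out) + 1L]] <- data.frame(
          cancer_type = ct, setting = setting, tier = tiers[ti],
          n_samples = n, cumulative_fraction = cum_n / n,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
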