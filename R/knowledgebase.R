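# Variant/drug knowledgebase: loading, validation, evidence ordering and
# duplicate resolution. The knowledgebase is a flat TSV where each row links
# one variant (exact mutation, ambiguous single-residue mutation, codon range,
# loose frameshift/nonsense category, expression direction, copy-number event
# or fusion) to one drug, in one tumor type, with an effect (sensitive or
# resistant) and an ordinal level of evidence.

KB_COLUMNS <- c("gene", "variant_class", "variant_spec", "tumor_type",
                "effect", "evidence_level", "drug", "drug_classes",
                "pubmed_id")

KB_VARIANT_CLASSES <- c("missense_exact", "missense_position", "aa_range",
                        "frameshift", "nonsense", "inframe_indel_exact",
                        "inframe_indel_range", "expression_high",
                        "expression_low", "cna", "cnl", "fusion")

# Classes whose variant_spec carries no amino-acid information
KB_SPECLESS_CLASSES <- c("expression_high", "expression_low", "cna", "cnl",
                         "fusion")

#' Evidence levels in increasing order of maturity
#'
#' The four ordinal tiers of support for a variant/drug interaction:
#' preclinical < case_report < clinical_trial < fda_approved.
#'
#' @return Character vector of the four level names, lowest first.
#' @export
evidence_levels <- function() {
  c("preclinical", "case_report", "clinical_trial", "fda_approved")
}

#' Ordinal rank of an evidence level
#'
#' @param level Character vector of evidence level names.
#' @return Integer rank(s): preclinical = 1 up to fda_approved = 4.
#' @examples
#' evidence_rank("fda_approved")  # 4
#' @export
evidence_rank <- function(level) {
  r <- match(level, evidence_levels())
  if (anyNA(r)) {
    stop("unknown evidence level(s): ",
         paste(unique(level[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  r
}

# Internal: validate a variant_spec against its class.
# Returns NULL if valid, otherwise a message.
validate_variant_spec <- function(variant_class, variant_spec) {
  spec <- if (is.na(variant_spec)) "" else as.character(variant_spec)
  ok_msg <- NULL
  if (variant_class %in% KB_SPECLESS_CLASSES) {
    if (nzchar(spec) && spec != "-")
      return(sprintf("class %s must carry no amino-acid spec (got '%s')",
                     variant_class, spec))
    return(NULL)
  }
  switch(variant_class,
    missense_exact = {
      if (!grepl("^[A-Z][0-9]+[A-Z]$", spec))
        ok_msg <- sprintf("bad missense_exact spec '%s'", spec)
    },
    missense_position = {
      if (!grepl("^[A-Z][0-9]+$", spec))
        ok_msg <- sprintf("bad missense_position spec '%s'", spec)
    },
    aa_range = ,
    inframe_indel_range = {
      m <- regmatches(spec,
            regexec("^([0-9]+)-([0-9]+)(:[a-z_]+)?$", spec))[[1]]
      if (length(m) == 0L) {
        ok_msg <- sprintf("bad range spec '%s'", spec)
      } else {
        a <- as.integer(m[2]); b <- as.integer(m[3])
        if (a < 1L || b < a)
          ok_msg <- sprintf("range spec '%s' needs 1 <= start <= end", spec)
      }
    },
    inframe_indel_exact = {
      if (!grepl("^[A-Z][0-9]+(_[A-Z][0-9]+)?(del|ins|dup|delins)", spec))
        ok_msg <- sprintf("bad inframe_indel_exact spec '%s'", spec)
    },
    frameshift = ,
    nonsense = {
      if (!(spec == "*" || grepl("^[A-Z]?[0-9]+$", spec)))
        ok_msg <- sprintf("bad %s spec '%s' (position or '*')",
                          variant_class, spec)
    },
    ok_msg <- sprintf("unknown variant class '%s'", variant_class)
  )
  ok_msg
}

#' Load and validate a variant/drug knowledgebase TSV
#'
#' Columns (in canonical order): gene, variant_class, variant_spec,
#' tumor_type, effect, evidence_level, drug, drug_classes (';'-separated),
#' pubmed_id. Unknown variant classes, malformed specs, and (when a class map
#' is supplied) drugs absent from the map are hard errors naming the
#' offending line.
#'
#' @param path Path to the knowledgebase TSV.
#' @param class_map Optional drug-class map (data.frame with columns `drug`,
#'   `class`, as from [read_drug_class_map()]). When supplied, the
#'   `drug_classes` field is filled from the map and every drug must be
#'   present in it.
#' @param tumor_type_vocab Optional character vector of allowed cancer-type
#'   codes; `UNSPECIFIED` is always allowed.
#' @return A data.frame of validated entries with an `entry_id` column
#'   (original file order).
#' @export
load_knowledgebase <- function(path, class_map = NULL,
                               tumor_type_vocab = NULL) {
  df <- read_tsv_file(path, required = KB_COLUMNS)
  if (nrow(df) == 0L) {
    warning("knowledgebase '", path, "' is empty", call. = FALSE)
    out <- df[, KB_COLUMNS, drop = FALSE]
    out$entry_id <- integer(0)
    return(out)
  }
  df <- df[, KB_COLUMNS, drop = FALSE]
  df$entry_id <- seq_len(nrow(df))
  df$variant_spec[is.na(df$variant_spec)] <- ""

  errs <- character(0)
  line_of <- function(i) i + 1L  # header is line 1
  for (i in seq_len(nrow(df))) {
    vc <- df$variant_class[i]
    if (!vc %in% KB_VARIANT_CLASSES) {
      errs <- c(errs, sprintf("line %d: unknown variant_class '%s'",
                              line_of(i), vc))
      next
    }
    msg <- validate_variant_spec(vc, df$variant_spec[i])
    if (!is.null(msg))
      errs <- c(errs, sprintf("line %d: %s", line_of(i), msg))
    if (!df$effect[i] %in% c("sensitive", "resistant"))
      errs <- c(errs, sprintf("line %d: bad effect '%s'",
                              line_of(i), df$effect[i]))
    if (!df$evidence_level[i] %in% evidence_levels())
      errs <- c(errs, sprintf("line %d: bad evidence_level '%s'",
                              line_of(i), df$evidence_level[i]))
    if (!is.null(tumor_type_vocab) &&
        !df$tumor_type[i] %in% c(tumor_type_vocab, "UNSPECIFIED"))
      errs <- c(errs, sprintf("line %d: tumor_type '%s' not in vocabulary",
                              line_of(i), df$tumor_type[i]))
  }
  if (!is.null(class_map)) {
    stopifnot(all(c("drug", "class") %in% names(class_map)))
    unmapped <- setdiff(unique(df$drug), unique(class_map$drug))
    if (length(unmapped) > 0L) {
      errs <- c(errs, paste0("drug(s) missing from class map: ",
                             paste(unmapped, collapse = ", ")))
    } else {
      df$drug_classes <- vapply(df$drug, function(d) {
        paste(sort(unique(class_map$class[class_map$drug == d])),
              collapse = ";")
      }, character(1))
    }
  }
  if (any(is.na(df$drug_classes) | !nzchar(df$drug_classes)))
    errs <- c(errs, "entries with empty drug_classes and no class map")
  if (length(errs) > 0L)
    stop("knowledgebase validation failed:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  message(nrow(df), " knowledgebase entries loaded from ", path)
  df
}

#' Resolve duplicate knowledgebase entries by evidence level
#'
#' Entries identical in (gene, variant_class, variant_spec, drug, tumor_type,
#' effect) are collapsed to the entry with the highest evidence level;
#' non-identical entries are all retained. A tie at the top level keeps the
#' first entry in file order and warns.
#'
#' @param entries Knowledgebase data.frame from [load_knowledgebase()].
#' @return The deduplicated data.frame (original relative order preserved).
#' @export
deduplicate_entries <- function(entries) {
  if (nrow(entries) <= 1L) return(entries)
  key <- paste(entries$gene, entries$variant_class, entries$variant_spec,
               entries$drug, entries$tumor_type, entries$effect, sep = "\r")
  rank <- evidence_rank(entries$evidence_level)
  keep <- logical(nrow(entries))
  ties <- character(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    top <- idx[rank[idx] == max(rank[idx])]
    if (length(top) > 1L)
      ties <- c(ties, sprintf("%s %s (%s)", entries$gene[top[1]],
                              entries$variant_spec[top[1]],
                              entries$drug[top[1]]))
    keep[top[1]] <- TRUE
  }
  if (length(ties) > 0L)
    warning("equal-evidence duplicate tie(s) resolved by file order: ",
            paste(ties, collapse = "; "), call. = FALSE)
  entries[keep, , drop = FALSE]
}

#' Write a knowledgebase table in canonical column order
#'
#' @param entries Knowledgebase data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_knowledgebase <- function(entries, path) {
  write_tsv_file(entries[, KB_COLUMNS, drop = FALSE], path)
}

#' Read a drug-class lookup table
#'
#' One row per (drug, class) pair; a drug may belong to several classes
#' (e.g. a dual HER2/EGFR inhibitor).
#'
#' @param path TSV with columns `drug`, `class`.
#' @return data.frame with columns `drug`, `class`.
#' @export
read_drug_class_map <- function(path) {
  read_tsv_file(path, required = c("drug", "class"))
}

# Internal: split the ';'-separated drug_classes field
split_drug_classes <- function(x) strsplit(as.character(x), ";", fixed = TRUE)
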