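# IQR-fence expression outlier scoring. For each druggable feature (gene or
# phosphosite) the cohort-wide first and third quartiles define an outlier
# score: (x - Q3)/IQR for the high direction, (Q1 - x)/IQR for the low
# direction. A score strictly greater than 1.5 calls the sample an outlier
# (the classical Tukey fence).

#' Cohort quartiles for one feature
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Missing values are ignored; fewer than
#' `min_n` non-missing values is an error (callers skip such features).
#'
#' @param values Numeric vector of the feature's expression across the
#'   cohort.
#' @param min_n Minimum number of non-missing values (default 4).
#' @return Named list with q1, q3, iqr.
#' @export
cohort_quartiles <- function(values, min_n = 4L) {
  v <- values[!is.na(values)]
  if (length(v) < min_n)
    stop("need at least ", min_n, " non-missing values", call. = FALSE)
  q <- stats::quantile(v, probs = c(0.25, 0.75), names = FALSE, type = 7)
  list(q1 = q[1], q3 = q[2], iqr = q[2] - q[1])
}

#' Outlier score for a single expression value
#'
#' @param x Expression value.
#' @param q1,q3,iqr Cohort statistics from [cohort_quartiles()].
#' @param direction "high" scores (x - Q3)/IQR; "low" scores (Q1 - x)/IQR.
#' @return The score; NA with a warning when iqr is 0 (degenerate feature).
#' @export
outlier_score <- function(x, q1, q3, iqr, direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (iqr <= 0) {
    warning("IQR is zero; outlier score undefined", call. = FALSE)
    return(rep(NA_real_, length(x)))
  }
  if (direction == "high") (x - q3) / iqr else (q1 - x) / iqr
}

# Internal: features of the kb linked to expression druggability, with the
# direction implied by the entry class.
kb_expression_features <- function(kb) {
  sub <- kb[kb$variant_class %in% c("expression_high", "expression_low"), ,
            drop = FALSE]
  if (nrow(sub) == 0L)
    return(empty_df(c("feature", "direction")))
  unique(data.frame(
    feature = sub$gene,
    direction = ifelse(sub$variant_class == "expression_high", "high", "low"),
    stringsAsFactors = FALSE))
}

#' Call expression outliers for knowledgebase-linked features
#'
#' Only features with a knowledgebase expression entry are scored (a
#' phosphosite row `GENE:pSNNN` inherits its parent gene's entry when
#' `inherit_phosphosites` is TRUE). Features observed in fewer than
#' `min_samples` samples are skipped; samples from excluded cancer types are
#' removed before quartiles are computed; degenerate (zero-IQR) features are
#' skipped with a warning.
#'
#' @param matrix Expression matrix from [read_expression_matrix()].
#' @param kb Resolved knowledgebase.
#' @param traits Traits data.frame (used for cancer-type exclusion); may be
#'   NULL when `exclude_cancer_types` is empty.
#' @param exclude_cancer_types Cancer-type codes removed before analysis
#'   (e.g. `"LAML"` to mirror leaving acute myeloid leukemia out).
#' @param min_samples Minimum non-missing samples per feature (default 10).
#' @param threshold Outlier fence in IQR units (default 1.5, strict `>`).
#' @param inherit_phosphosites Let `GENE:pSNNN` rows use GENE's entry.
#' @param keep_all_scores If TRUE return every scored cell, not only
#'   outliers.
#' @return data.frame of outlier calls: sample_id, feature, level, x, q1,
#'   q3, iqr, score, direction, is_outlier.
#' @export
call_outliers <- function(matrix, kb, traits = NULL,
                          exclude_cancer_types = character(0),
                          min_samples = 10L, threshold = 1.5,
                          inherit_phosphosites = TRUE,
                          keep_all_scores = FALSE) {
  level <- attr(matrix, "level")
  if (is.null(level)) level <- "mrna"
  if (length(exclude_cancer_types) > 0L) {
    stopifnot(!is.null(traits))
    keep_samples <- traits$sample_id[!traits$cancer_type %in%
                                       exclude_cancer_types]
    matrix <- matrix[, colnames(matrix) %in% keep_samples, drop = FALSE]
  }
  feats <- kb_expression_features(kb)
  rows <- list()
  for (i in seq_len(nrow(feats))) {
    gene <- feats$feature[i]
    direction <- feats$direction[i]
    targets <- rownames(matrix)[rownames(matrix) == gene]
    if (inherit_phosphosites) {
      targets <- c(targets, grep(paste0("^", gene, ":"), rownames(matrix),
                                 value = TRUE))
    }
    if (length(targets) == 0L) {
      message("call_outliers: feature ", gene, " absent from matrix; skipped")
      next
    }
    for (feature in targets) {
      v <- matrix[feature, ]
      n <- sum(!is.na(v))
      if (n < min_samples) {
        message("call_outliers: feature ", feature, " present in only ", n,
                " samples; skipped")
        next
      }
      qs <- cohort_quartiles(v)
      if (qs$iqr <= 0) {
        warning("call_outliers: feature ", feature,
                " has zero IQR (degenerate); skipped", call. = FALSE)
        next
      }
      score <- outlier_score(v, qs$q1, qs$q3, qs$iqr, direction)
      df <- data.frame(
        sample_id = colnames(matrix), feature = feature, level = level,
        x = unname(v), q1 = qs$q1, q3 = qs$q3, iqr = qs$iqr,
        score = unname(score), direction = direction,
        is_outlier = !is.na(score) & score > threshold,
        stringsAsFactors = FALSE)
      df <- df[!is.na(df$x), , drop = FALSE]
      if (!keep_all_scores) df <- df[df$is_outlier, , drop = FALSE]
      rows[[length(rows) + 1L]] <- df
    }
  }
  if (length(rows) == 0L)
    return(empty_df(c("sample_id", "feature", "level", "x", "q1", "q3",
                      "iqr", "score", "direction", "is_outlier")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank outlier calls within each tumor sample
#'
#' Dense rank per sample, 1 = highest score; tied scores share a rank. Used
#' to surface the most promising druggable target per tumor.
#'
#' @param calls Outlier calls from [call_outliers()].
#' @return `calls` with a `rank_in_sample` column.
#' @export
rank_within_sample <- function(calls) {
  if (nrow(calls) == 0L) {
    calls$rank_in_sample <- integer(0)
    return(calls)
  }
  calls$rank_in_sample <- NA_integer_
  for (s in unique(calls$sample_id)) {
    idx <- which(calls$sample_id == s)
    sc <- calls$score[idx]
    # dense rank descending: rank 1 for the largest distinct score
    calls$rank_in_sample[idx] <- match(sc, sort(unique(sc),
                                                decreasing = TRUE))
  }
  calls
}
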