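# Independent reference implementations ("oracles") used to cross-check the
# package. These deliberately avoid the package's code paths: matching is a
# literal row scan over parsed entries, clustering uses explicit component
# expansion + Floyd-Warshall + literal recursion, the Mann-Whitney p-value
# enumerates every rank assignment, Fisher sums the hypergeometric density,
# and BH is computed by hand.

# ---- knowledgebase matching oracle -----------------------------------------

# Parse kb entries once into flat columns for the scan
oracle_parse_kb <- function(kb) {
  n <- nrow(kb)
  out <- data.frame(gene = kb$gene, vc = kb$variant_class,
                    spec = kb$variant_spec, effect = kb$effect,
                    evidence = kb$evidence_level, drug = kb$drug,
                    tumor_type = kb$tumor_type,
                    lo = NA_integer_, hi = NA_integer_,
                    restrict = NA_character_, pos = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (out$vc[i] %in% c("aa_range", "inframe_indel_range")) {
      m <- regmatches(out$spec[i],
            regexec("^([0-9]+)-([0-9]+)(:([a-z_]+))?$", out$spec[i]))[[1]]
      out$lo[i] <- as.integer(m[2]); out$hi[i] <- as.integer(m[3])
      if (nzchar(m[5])) out$restrict[i] <- m[5]
    } else if (out$vc[i] %in% c("frameshift", "nonsense") &&
               out$spec[i] != "*") {
      out$pos[i] <- as.integer(sub("^[A-Z]?", "", out$spec[i]))
    }
  }
  out
}

# Literal scan implementing the three matching routes + loose categories
oracle_match <- function(record, pk) {
  pc <- record$protein_change
  m <- regmatches(pc, regexec("^([A-Z])([0-9]+)", pc))[[1]]
  ref <- if (length(m) == 3L) m[2] else NA_character_
  pos <- if (length(m) == 3L) as.integer(m[3]) else NA_integer_
  hits <- integer(0)
  for (i in seq_len(nrow(pk))) {
    if (pk$gene[i] != record$gene) next
    vc <- pk$vc[i]
    hit <- FALSE
    if (vc == "missense_exact") {
      hit <- record$mutation_class == "missense" && pk$spec[i] == pc
    } else if (vc == "inframe_indel_exact") {
      hit <- record$mutation_class %in% c("inframe_del", "inframe_ins") &&
        pk$spec[i] == pc
    } else if (vc == "missense_position") {
      hit <- record$mutation_class == "missense" && !is.na(pos) &&
        pk$spec[i] == paste0(ref, pos)
    } else if (vc %in% c("aa_range", "inframe_indel_range")) {
      classes <- if (!is.na(pk$restrict[i])) pk$restrict[i] else
        if (vc == "inframe_indel_range") c("inframe_del", "inframe_ins")
        else c("missense", "inframe_del", "inframe_ins")
      hit <- record$mutation_class %in% classes && !is.na(pos) &&
        pos >= pk$lo[i] && pos <= pk$hi[i]
    } else if (vc %in% c("frameshift", "nonsense")) {
      hit <- record$mutation_class == vc &&
        (pk$spec[i] == "*" || (!is.na(pos) && !is.na(pk$pos[i]) &&
                                 pos == pk$pos[i]))
    }
    if (hit) hits <- c(hits, i)
  }
  hits
}

# Literal resolution: sensitive-over-resistant, global max evidence,
# alphabetically first drug, specificity on exact cancer-type code
oracle_resolve <- function(hits, pk, cancer_type) {
  if (length(hits) == 0L) return(NULL)
  sub <- pk[hits, , drop = FALSE]
  effect <- if ("sensitive" %in% sub$effect) "sensitive" else "resistant"
  sub <- sub[sub$effect == effect, , drop = FALSE]
  lv <- c(preclinical = 1, case_report = 2, clinical_trial = 3,
          fda_approved = 4)
  r <- lv[sub$evidence]
  top <- sub[r == max(r), , drop = FALSE]
  list(effect = effect,
       chosen_drug = sort(unique(top$drug))[1],
       chosen_evidence = names(lv)[max(r)],
       specificity = if (cancer_type %in%
                           setdiff(unique(top$tumor_type), "UNSPECIFIED"))
         "cancer_type_specific" else "non_specific")
}

# ---- random cohort generators for matching equivalence ---------------------

random_kb <- function(n_entries, genes = c("G1", "G2", "G3", "G4")) {
  aa <- LETTERS[1:20]
  classes <- c("missense_exact", "missense_position", "aa_range",
               "inframe_indel_range", "frameshift", "nonsense",
               "inframe_indel_exact")
  rows <- lapply(seq_len(n_entries), function(i) {
    vc <- sample(classes, 1)
    spec <- switch(vc,
      missense_exact = paste0(sample(aa, 1), sample(1:40, 1),
                              sample(aa, 1)),
      missense_position = paste0(sample(aa, 1), sample(1:40, 1)),
      aa_range = , inframe_indel_range = {
        lo <- sample(1:30, 1)
        paste0(lo, "-", lo + sample(1:10, 1))
      },
      inframe_indel_exact = {
        p <- sample(1:40, 1)
        paste0(sample(aa, 1), p, "_", sample(aa, 1), p + 2, "del")
      },
      frameshift = , nonsense = if (stats::runif(1) < 0.3) "*" else
        paste0(sample(aa, 1), sample(1:40, 1)))
    data.frame(gene = sample(genes, 1), variant_class = vc,
               variant_spec = spec,
               tumor_type = sample(c("CT1", "CT2", "CT3", "UNSPECIFIED"), 1),
               effect = sample(c("sensitive", "resistant"), 1,
                               prob = c(0.7, 0.3)),
               evidence_level = sample(evidence_levels(), 1),
               drug = paste0("drug", sample(1:8, 1)),
               drug_classes = "classX", pubmed_id = "t",
               stringsAsFactors = FALSE)
  })
  kb <- do.call(rbind, rows)
  kb$entry_id <- seq_len(nrow(kb))
  kb
}

random_records <- function(n, genes = c("G1", "G2", "G3", "G4")) {
  aa <- LETTERS[1:20]
  rows <- lapply(seq_len(n), function(i) {
    cls <- sample(c("missense", "inframe_del", "inframe_ins", "frameshift",
                    "nonsense"), 1, prob = c(0.6, 0.1, 0.05, 0.15, 0.1))
    pos <- sample(1:40, 1)
    pc <- switch(cls,
      missense = paste0(sample(aa, 1), pos, sample(aa, 1)),
      inframe_del = paste0(sample(aa, 1), pos, "_", sample(aa, 1), pos + 2,
                           "del"),
      inframe_ins = paste0(sample(aa, 1), pos, "_", sample(aa, 1), pos + 1,
                           "ins", sample(aa, 1)),
      frameshift = paste0(sample(aa, 1), pos, "Rfs*", sample(2:9, 1)),
      nonsense = paste0(sample(aa, 1), pos, "*"))
    data.frame(sample_id = sprintf("S%03d", sample(1:50, 1)),
               cancer_type = sample(c("CT1", "CT2", "CT3"), 1),
               gene = sample(genes, 1), protein_change = pc,
               mutation_class = cls, indel_length = 0L,
               population_af = NA_real_, pathogenic_flag = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- clustering oracle -----------------------------------------------------

# Exhaustive reference: explicit component expansion, Floyd-Warshall
# shortest paths, literal recursion. Returns a list of clusters
# (members sorted, centroid, generation).
oracle_cluster <- function(distances, mutations, p_cut = 0.05, d_cut = 5,
                           radius = 5) {
  bg <- distances$distance_A
  res <- unique(mutations$residue)
  pairs <- distances[distances$res_i %in% res & distances$res_j %in% res, ,
                     drop = FALSE]
  if (nrow(pairs) > 0L) {
    pairs$p <- vapply(pairs$distance_A, function(d) mean(bg <= d),
                      numeric(1))
    pairs <- pairs[pairs$p < p_cut & pairs$distance_A < d_cut, ,
                   drop = FALSE]
  }
  rec <- stats::setNames(as.numeric(mutations$recurrence),
                         as.character(mutations$residue))
  clusters <- list()
  recurse <- function(members, gen) {
    sub <- pairs[pairs$res_i %in% members & pairs$res_j %in% members, ,
                 drop = FALSE]
    if (nrow(sub) == 0L) return(invisible(NULL))
    verts <- sort(unique(c(sub$res_i, sub$res_j)))
    unvisited <- verts
    comps <- list()
    while (length(unvisited) > 0L) {
      comp <- unvisited[1]
      repeat {
        nb <- unique(c(sub$res_j[sub$res_i %in% comp],
                       sub$res_i[sub$res_j %in% comp]))
        new <- setdiff(nb, comp)
        if (length(new) == 0L) break
        comp <- c(comp, new)
      }
      comp <- sort(comp)
      comps[[length(comps) + 1L]] <- comp
      unvisited <- setdiff(unvisited, comp)
    }
    comps <- comps[order(vapply(comps, min, numeric(1)))]
    for (comp in comps) {
      n <- length(comp)
      D <- matrix(Inf, n, n); diag(D) <- 0
      for (r in seq_len(nrow(sub))) {
        ii <- match(sub$res_i[r], comp); jj <- match(sub$res_j[r], comp)
        if (!is.na(ii) && !is.na(jj)) {
          D[ii, jj] <- min(D[ii, jj], sub$distance_A[r])
          D[jj, ii] <- D[ii, jj]
        }
      }
      for (k in 1:n) for (i in 1:n) for (j in 1:n)
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      rc <- rec[as.character(comp)]
      rc[is.na(rc)] <- 0
      cand <- which(rc == max(rc))
      if (length(cand) > 1L) {
        sc <- vapply(cand, function(ci) sum(D[ci, ] * rc), numeric(1))
        cand <- cand[sc == min(sc)]
      }
      cen_i <- min(cand)
      inside <- comp[D[cen_i, ] <= radius]
      clusters[[length(clusters) + 1L]] <<- list(
        members = sort(inside), centroid = comp[cen_i], generation = gen)
      leftover <- setdiff(comp, inside)
      if (length(leftover) > 1L) recurse(leftover, gen + 1L)
    }
    invisible(NULL)
  }
  recurse(res, 0L)
  clusters
}

# Canonical form for comparing cluster outputs
canonical_clusters <- function(cl_list) {
  out <- lapply(cl_list, function(cl)
    list(members = as.integer(cl$members),
         centroid = as.integer(cl$centroid),
         generation = as.integer(cl$generation)))
  out[order(vapply(out, function(x) min(x$members), integer(1)),
            vapply(out, function(x) x$generation, integer(1)))]
}

# Tidy cluster df -> same canonical list
tidy_to_clusters <- function(df) {
  if (nrow(df) == 0L) return(list())
  ids <- unique(df$cluster_id)
  canonical_clusters(lapply(ids, function(i) {
    sub <- df[df$cluster_id == i, , drop = FALSE]
    list(members = sort(sub$residue),
         centroid = sub$residue[sub$centroid_flag],
         generation = sub$generation[1])
  }))
}

random_structure <- function(n_res, box = 15) {
  coords <- matrix(stats::runif(n_res * 3, 0, box), ncol = 3)
  pr <- t(utils::combn(n_res, 2))
  data.frame(structure_id = "RND", gene = "G",
             res_i = pr[, 1], res_j = pr[, 2],
             distance_A = sqrt(rowSums((coords[pr[, 1], , drop = FALSE] -
                                          coords[pr[, 2], ,
                                                 drop = FALSE])^2)),
             stringsAsFactors = FALSE)
}

# ---- statistics oracles ----------------------------------------------------

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
mw_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(n + m, n)
  us <- apply(idx, 2, function(ix) sum(rk[ix]) - n * (n + 1) / 2)
  p_lo <- mean(us <= u_obs + 1e-9)
  p_hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# Two-sided Fisher exact p by hypergeometric summation over the 2x2 table
# [[a, b], [c, d]]
fisher_oracle <- function(a, b, c, d) {
  col1 <- a + c; col2 <- b + d; row1 <- a + b
  support <- max(0, row1 - col2):min(row1, col1)
  dens <- stats::dhyper(support, col1, col2, row1)
  p_obs <- stats::dhyper(a, col1, col2, row1)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by hand
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}
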