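# Recursive 3D proximity clustering of mutated residues on protein
# structures. Pairwise residue distances give an empirical background; a
# pair's p-value is the proportion of background distances less than or
# equal to it. Significant proximal pairs (p < 0.05 and distance < 5 A) are
# single-link clustered; each cluster is focused to a 5 A graph radius
# around a recurrence-weighted centroid, and members left outside the radius
# are re-clustered until no significant pair remains. Uncatalogued mutations
# co-clustered with known drug-sensitive (or drug-resistant) mutations
# become putative drug-response mutations.

#' Read a precomputed residue-pair distance table
#'
#' @param path TSV with columns structure_id, gene, res_i, res_j,
#'   distance_A. Each unordered residue pair appears once.
#' @return data.frame of distances.
#' @export
read_distance_table <- function(path) {
  df <- read_tsv_file(path, required = c("structure_id", "gene", "res_i",
                                         "res_j", "distance_A"))
  df$res_i <- as.integer(df$res_i)
  df$res_j <- as.integer(df$res_j)
  df$distance_A <- as.numeric(df$distance_A)
  if (any(df$distance_A < 0)) stop("negative distances", call. = FALSE)
  df
}

#' Residue-pair distances from a PDB file
#'
#' Residue-residue distance is the minimum inter-atomic distance between the
#' two residues. Requires the bio3d package.
#'
#' @param pdb_path Path to a PDB file.
#' @param chain Chain identifier (default "A").
#' @param structure_id,gene Labels for the output table.
#' @return data.frame in the [read_distance_table()] layout.
#' @export
pdb_residue_distances <- function(pdb_path, chain = "A",
                                  structure_id = basename(pdb_path),
                                  gene = NA_character_) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("bio3d is required for PDB input; supply a distance TSV instead",
         call. = FALSE)
  pdb <- bio3d::read.pdb(pdb_path)
  sel <- bio3d::atom.select(pdb, chain = chain)
  atoms <- pdb$atom[sel$atom, , drop = FALSE]
  resnos <- sort(unique(atoms$resno))
  coords <- split(atoms[, c("x", "y", "z")], atoms$resno)
  out <- list()
  for (a in seq_len(length(resnos) - 1L)) {
    xa <- as.matrix(coords[[as.character(resnos[a])]])
    for (b in (a + 1L):length(resnos)) {
      xb <- as.matrix(coords[[as.character(resnos[b])]])
      d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
      out[[length(out) + 1L]] <- data.frame(
        structure_id = structure_id, gene = gene,
        res_i = resnos[a], res_j = resnos[b],
        distance_A = sqrt(max(min(d2), 0)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Empirical p-value of a residue-pair distance
#'
#' The proportion of all pairwise residue distances on the structure that
#' are less than or equal to the distance in question.
#'
#' @param d Distance(s) in Angstrom.
#' @param background Numeric vector of all pairwise distances on the
#'   structure (includes the pair itself).
#' @return p-value(s) in (0, 1].
#' @export
pair_pvalue <- function(d, background) {
  if (length(background) == 0L)
    stop("empty background distance distribution", call. = FALSE)
  vapply(d, function(x) sum(background <= x) / length(background),
         numeric(1))
}

#' Significant proximal pairs among mutated residues
#'
#' Pairs of mutated residues retained iff p < `p_cutoff` and distance <
#' `dist_cutoff` (both strict). The background is every residue pair of the
#' structure, mutated or not.
#'
#' @param mutated_residues Integer vector of residue positions carrying
#'   cohort or knowledgebase mutations.
#' @param distances Distance data.frame for one structure
#'   (res_i, res_j, distance_A).
#' @param p_cutoff,dist_cutoff Thresholds (defaults 0.05 and 5 A).
#' @return data.frame res_i, res_j, distance_A, p_value of retained pairs.
#' @export
significant_pairs <- function(mutated_residues, distances,
                              p_cutoff = 0.05, dist_cutoff = 5) {
  background <- distances$distance_A
  sub <- distances[distances$res_i %in% mutated_residues &
                     distances$res_j %in% mutated_residues, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(empty_df(c("res_i", "res_j", "distance_A", "p_value")))
  sub$p_value <- pair_pvalue(sub$distance_A, background)
  out <- sub[sub$p_value < p_cutoff & sub$distance_A < dist_cutoff,
             c("res_i", "res_j", "distance_A", "p_value"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# Internal: igraph over significant pairs (vertex names = residue numbers,
# edge weights = distances)
pair_graph <- function(pairs, vertices = NULL) {
  verts <- unique(c(vertices, pairs$res_i, pairs$res_j))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = as.character(verts))
  if (nrow(pairs) > 0L) {
    g <- igraph::add_edges(
      g, rbind(as.character(pairs$res_i), as.character(pairs$res_j)),
      weight = pairs$distance_A)
  }
  g
}

#' Single-link clustering of significant pairs
#'
#' Initial clusters are the connected components of the significant-pair
#' graph (single-link agglomeration reaches exactly the components).
#'
#' @param pairs Significant pairs from [significant_pairs()].
#' @return List of integer vectors (residues per initial cluster), sorted
#'   for determinism; empty list when no pairs exist.
#' @export
single_link_cluster <- function(pairs) {
  if (nrow(pairs) == 0L) return(list())
  g <- pair_graph(pairs)
  comp <- igraph::components(g)
  membership <- unname(split(as.integer(igraph::V(g)$name),
                             comp$membership))
  membership <- lapply(membership, sort)
  membership[order(vapply(membership, min, integer(1)))]
}

#' Choose a cluster centroid
#'
#' The member with the highest cohort recurrence; ties are broken by the
#' minimal recurrence-weighted sum of shortest-path distances to all other
#' members (closest to the highly recurrent mass), then by the lowest
#' residue number.
#'
#' @param members Integer vector of cluster residues.
#' @param pairs Significant pairs restricted to (at least) these members.
#' @param recurrence Named numeric vector: residue -> cohort recurrence
#'   count. Missing residues count 0.
#' @return The centroid residue (integer).
#' @export
choose_centroid <- function(members, pairs, recurrence) {
  stopifnot(length(members) > 0L)
  if (length(members) == 1L) return(members)
  rec <- recurrence[as.character(members)]
  rec[is.na(rec)] <- 0
  top <- members[rec == max(rec)]
  if (length(top) == 1L) return(top)
  g <- pair_graph(pairs[pairs$res_i %in% members &
                          pairs$res_j %in% members, , drop = FALSE],
                  vertices = members)
  sp <- igraph::distances(g, v = as.character(top),
                          to = as.character(members))
  w <- recurrence[as.character(members)]
  w[is.na(w)] <- 0
  score <- as.numeric(sp %*% w)  # weighted distance to the recurrent mass
  best <- top[score == min(score)]
  min(best)
}

#' Focus a cluster to a graph radius and recurse on the remainder
#'
#' The focused cluster keeps the centroid plus every member within
#' `radius_limit` of it along shortest paths over significant-pair edges.
#' Members outside the radius re-enter single-link clustering restricted to
#' pairs among themselves; the recursion ends when no significant pair
#' remains, and each round increments the generation counter.
#'
#' @param members Integer vector: residues of one initial cluster.
#' @param pairs Significant pairs (at least those among `members`).
#' @param recurrence Named recurrence vector (see [choose_centroid()]).
#' @param radius_limit Graph radius in Angstrom (default 5).
#' @param generation Starting generation (default 0).
#' @return List of clusters; each a list with members, centroid,
#'   generation, and dist_to_centroid (named numeric).
#' @export
focus_and_recurse <- function(members, pairs, recurrence, radius_limit = 5,
                              generation = 0L) {
  sub <- pairs[pairs$res_i %in% members & pairs$res_j %in% members, ,
               drop = FALSE]
  comps <- single_link_cluster(sub)
  clusters <- list()
  for (comp in comps) {
    centroid <- choose_centroid(comp, sub, recurrence)
    g <- pair_graph(sub[sub$res_i %in% comp & sub$res_j %in% comp, ,
                        drop = FALSE], vertices = comp)
    sp <- igraph::distances(g, v = as.character(centroid),
                            to = as.character(comp))[1, ]
    names(sp) <- as.character(comp)
    inside <- comp[sp <= radius_limit]
    clusters[[length(clusters) + 1L]] <- list(
      members = sort(inside), centroid = centroid,
      generation = generation,
      dist_to_centroid = sp[as.character(sort(inside))])
    leftover <- setdiff(comp, inside)
    if (length(leftover) > 1L) {
      clusters <- c(clusters,
                    focus_and_recurse(leftover, sub, recurrence,
                                      radius_limit, generation + 1L))
    }
  }
  clusters
}

#' Cluster one structure's mutated residues
#'
#' Runs the full chain: significant pairs, single-link components, centroid
#' focusing and recursion. Mutation metadata (name, recurrence,
#' knowledgebase label) is carried onto the members.
#'
#' @param distances Distance table for one structure.
#' @param mutations data.frame with columns residue, mutation (protein
#'   change), recurrence, and kb_label (one of "sensitive", "resistant", or
#'   NA for uncatalogued); optional column drug (the known mutation's drug).
#' @param p_cutoff,dist_cutoff,radius_limit Clustering thresholds
#'   (defaults 0.05, 5 A, 5 A).
#' @return Tidy data.frame: cluster_id, structure_id, gene, generation,
#'   residue, mutation, recurrence, kb_label, centroid_flag,
#'   dist_to_centroid_A.
#' @export
cluster_structure <- function(distances, mutations, p_cutoff = 0.05,
                              dist_cutoff = 5, radius_limit = 5) {
  structure_id <- unique(distances$structure_id)
  gene <- unique(distances$gene)
  stopifnot(length(structure_id) == 1L, length(gene) == 1L)
  rec <- setNames(as.numeric(mutations$recurrence),
                  as.character(mutations$residue))
  pairs <- significant_pairs(unique(mutations$residue), distances,
                             p_cutoff, dist_cutoff)
  clusters <- focus_and_recurse(unique(c(pairs$res_i, pairs$res_j)), pairs,
                                rec, radius_limit)
  if (length(clusters) == 0L)
    return(empty_df(c("cluster_id", "structure_id", "gene", "generation",
                      "residue", "mutation", "recurrence", "kb_label",
                      "centroid_flag", "dist_to_centroid_A")))
  out <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    idx <- match(cl$members, mutations$residue)
    out[[ci]] <- data.frame(
      cluster_id = paste0(structure_id, ".c", ci),
      structure_id = structure_id, gene = gene,
      generation = cl$generation, residue = cl$members,
      mutation = mutations$mutation[idx],
      recurrence = mutations$recurrence[idx],
      kb_label = mutations$kb_label[idx],
      drug = if ("drug" %in% names(mutations)) mutations$drug[idx]
             else NA_character_,
      centroid_flag = cl$members == cl$centroid,
      dist_to_centroid_A = unname(cl$dist_to_centroid),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Label putative drug-response mutations from clusters
#'
#' Uncatalogued members of a cluster containing at least one known sensitive
#' mutation become putative_sensitive. Clusters containing known resistant
#' mutations yield putative_resistant members only if the cluster shares no
#' (gene, residue) with any sensitive-containing cluster. A cluster holding
#' both known sensitive and known resistant members is treated as sensitive
#' and the conflict is reported.
#'
#' @param clusters Tidy cluster table from [cluster_structure()] (may span
#'   several structures/genes via rbind).
#' @return data.frame of putative calls: gene, structure_id, cluster_id,
#'   residue, mutation, putative_label, linked_drug (the alphabetically
#'   first drug of the cluster's known members).
#' @export
propagate_labels <- function(clusters) {
  if (nrow(clusters) == 0L)
    return(empty_df(c("gene", "structure_id", "cluster_id", "residue",
                      "mutation", "putative_label", "linked_drug")))
  out <- list()
  ids <- unique(clusters$cluster_id)
  has_label <- function(cl, lab) any(!is.na(cl$kb_label) & cl$kb_label == lab)
  sens_ids <- ids[vapply(ids, function(i)
    has_label(clusters[clusters$cluster_id == i, ], "sensitive"),
    logical(1))]
  sens_keys <- with(clusters[clusters$cluster_id %in% sens_ids, ,
                             drop = FALSE],
                    paste(gene, residue))
  for (i in ids) {
    cl <- clusters[clusters$cluster_id == i, , drop = FALSE]
    sens <- has_label(cl, "sensitive")
    resi <- has_label(cl, "resistant")
    if (sens && resi)
      warning("cluster ", i, " contains both sensitive and resistant ",
              "known mutations; labeled sensitive", call. = FALSE)
    if (sens) {
      label <- "putative_sensitive"
    } else if (resi) {
      overlap <- any(paste(cl$gene, cl$residue) %in% sens_keys)
      if (overlap) next  # resistant cluster overlapping a sensitive one
      label <- "putative_resistant"
    } else next  # no known member, no putative calls
    known <- cl[!is.na(cl$kb_label), , drop = FALSE]
    linked <- sort(known$drug[!is.na(known$drug)])
    novel <- cl[is.na(cl$kb_label), , drop = FALSE]
    if (nrow(novel) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      gene = novel$gene, structure_id = novel$structure_id,
      cluster_id = novel$cluster_id, residue = novel$residue,
      mutation = novel$mutation, putative_label = label,
      linked_drug = if (length(linked) > 0L) linked[1] else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(empty_df(c("gene", "structure_id", "cluster_id", "residue",
                      "mutation", "putative_label", "linked_drug")))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Turn putative cluster mutations into tumor-level druggability calls
#'
#' Cohort mutation records whose (gene, protein change) matches a putative
#' cluster mutation produce calls at data level `cluster_putative` with
#' evidence tier `hotspot3d` (below preclinical in cumulative summaries).
#'
#' @param putative Putative calls from [propagate_labels()].
#' @param records Cohort mutation records.
#' @return Druggability-call data.frame (same columns as
#'   [annotate_cohort()]).
#' @export
putative_druggability_calls <- function(putative, records) {
  cols <- c("sample_id", "cancer_type", "gene", "variant_key", "data_level",
            "effect", "specificity", "chosen_drug", "chosen_evidence",
            "all_matches")
  if (nrow(putative) == 0L || nrow(records) == 0L) return(empty_df(cols))
  key <- paste(records$gene, records$protein_change, sep = ":")
  pkey <- paste(putative$gene, putative$mutation, sep = ":")
  idx <- match(key, pkey)
  hit <- !is.na(idx)
  if (!any(hit)) return(empty_df(cols))
  data.frame(
    sample_id = records$sample_id[hit],
    cancer_type = records$cancer_type[hit],
    gene = records$gene[hit],
    variant_key = key[hit],
    data_level = "cluster_putative",
    effect = ifelse(putative$putative_label[idx[hit]] == "putative_sensitive",
                    "sensitive", "resistant"),
    specificity = "non_specific",
    chosen_drug = putative$linked_drug[idx[hit]],
    chosen_evidence = "hotspot3d",
    all_matches = putative$cluster_id[idx[hit]],
    stringsAsFactors = FALSE)
}
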