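# Small helper: distance table for points on a line
line_distances <- function(positions, residues = seq_along(positions)) {
  pr <- t(utils::combn(length(positions), 2))
  data.frame(structure_id = "LINE", gene = "G",
             res_i = residues[pr[, 1]], res_j = residues[pr[, 2]],
             distance_A = abs(positions[pr[, 1]] - positions[pr[, 2]]),
             stringsAsFactors = FALSE)
}

test_that("pair p-value is the background proportion at or below d", {
  d <- line_distances(c(0, 3, 10, 20))
  bg <- d$distance_A  # {3, 10, 20, 7, 17, 10}
  expect_equal(pair_pvalue(3, bg), 1 / 6)
  expect_equal(pair_pvalue(min(bg) - 1e-9, bg) * length(bg), 0)
  expect_equal(pair_pvalue(min(bg), bg), 1 / 6)
  expect_equal(pair_pvalue(max(bg), bg), 1)
  expect_error(pair_pvalue(1, numeric(0)), "empty background")
})

test_that("significant pairs require both p < 0.05 and distance < 5", {
  # 40 residues: one tight pair, the rest far apart
  pos <- c(0, 4.2, seq(100, by = 15, length.out = 38))
  d <- line_distances(pos)
  sp <- significant_pairs(c(1, 2), d)
  expect_equal(nrow(sp), 1L)
  expect_lt(sp$p_value, 0.05)
  # distance >= 5 dropped even if p is tiny
  pos2 <- c(0, 6, seq(100, by = 15, length.out = 38))
  sp2 <- significant_pairs(c(1, 2), line_distances(pos2))
  expect_equal(nrow(sp2), 0L)
  # p >= 0.05 dropped even when distance < 5: tiny background
  d3 <- line_distances(c(0, 4.2, 4.4, 4.6))  # all six distances <= 4.6
  sp3 <- significant_pairs(1:4, d3, p_cutoff = 0.05)
  expect_equal(nrow(sp3), 0L)  # every p >= 1/6 > 0.05
})

test_that("single-link clusters are the connected components", {
  pairs <- data.frame(res_i = c(1L, 2L), res_j = c(2L, 3L),
                      distance_A = c(1, 1), p_value = 0.01)
  expect_equal(single_link_cluster(pairs), list(c(1L, 2L, 3L)))
  pairs2 <- data.frame(res_i = c(1L, 3L), res_j = c(2L, 4L),
                       distance_A = 1, p_value = 0.01)
  expect_equal(single_link_cluster(pairs2), list(c(1L, 2L), c(3L, 4L)))
  expect_equal(single_link_cluster(pairs2[0, ]), list())
})

test_that("centroid is the most recurrent member, geometry breaks ties", {
  pairs <- data.frame(res_i = c(600L, 600L), res_j = c(601L, 596L),
                      distance_A = c(2, 3), p_value = 0.01)
  rec <- c("600" = 40, "601" = 2, "596" = 1)
  expect_equal(choose_centroid(c(596L, 600L, 601L), pairs, rec), 600L)
  # equal recurrence: the graph-central member wins (path 1-2-3)
  pairs2 <- data.frame(res_i = c(1L, 2L), res_j = c(2L, 3L),
                       distance_A = c(1, 1), p_value = 0.01)
  rec2 <- c("1" = 1, "2" = 1, "3" = 1)
  # weighted distance sums: node 2 has 1+0+1=2, nodes 1 and 3 have 3
  expect_equal(choose_centroid(1:3, pairs2, rec2), 2L)
  # singleton cluster is its own centroid
  expect_equal(choose_centroid(7L, pairs2[0, ], rec2), 7L)
})

test_that("the 3-node chain focuses to {centroid, neighbor} and stops", {
  pairs <- data.frame(res_i = c(1L, 2L), res_j = c(2L, 3L),
                      distance_A = c(4, 4), p_value = 0.01)
  rec <- c("1" = 10, "2" = 1, "3" = 1)  # centroid is residue 1
  out <- focus_and_recurse(1:3, pairs, rec, radius_limit = 5)
  expect_length(out, 1L)
  expect_equal(out[[1]]$members, c(1L, 2L))  # 3 is 8 A away by path
  expect_equal(out[[1]]$centroid, 1L)
  expect_equal(out[[1]]$generation, 0L)
})

test_that("a bridged double hotspot splits after one recursion", {
  pairs <- data.frame(
    res_i = c(1L, 1L, 2L, 4L, 4L, 5L, 3L),
    res_j = c(2L, 3L, 3L, 5L, 6L, 6L, 4L),
    distance_A = c(1, 1, 1, 1, 1, 1, 4.5), p_value = 0.01)
  rec <- c("1" = 10, "2" = 1, "3" = 1, "4" = 1, "5" = 1, "6" = 1)
  out <- focus_and_recurse(1:6, pairs, rec, radius_limit = 5)
  expect_length(out, 2L)
  expect_equal(out[[1]]$members, c(1L, 2L, 3L))
  expect_equal(out[[1]]$generation, 0L)
  expect_equal(out[[2]]$members, c(4L, 5L, 6L))
  expect_equal(out[[2]]$generation, 1L)
})

test_that("all members within the radius give one cluster, no recursion", {
  pairs <- data.frame(res_i = c(1L, 1L), res_j = c(2L, 3L),
                      distance_A = c(2, 2), p_value = 0.01)
  rec <- c("1" = 5, "2" = 1, "3" = 1)
  out <- focus_and_recurse(1:3, pairs, rec, radius_limit = 5)
  expect_length(out, 1L)
  expect_equal(out[[1]]$members, 1:3)
})

test_that("clustering matches the exhaustive oracle on random structures", {
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(6:15, 1)
    d <- random_structure(n)
    muts <- data.frame(residue = seq_len(n),
                       mutation = paste0("M", seq_len(n)),
                       recurrence = sample(1:10, n, replace = TRUE),
                       kb_label = NA_character_,
                       stringsAsFactors = FALSE)
    got <- tidy_to_clusters(cluster_structure(d, muts))
    want <- canonical_clusters(oracle_cluster(d, muts))
    expect_equal(got, want)
  }
})

test_that("final clusters partition their members", {
  set.seed(14)
  for (rep in 1:10) {
    d <- random_structure(12, box = 10)
    muts <- data.frame(residue = 1:12, mutation = paste0("M", 1:12),
                       recurrence = sample(1:5, 12, replace = TRUE),
                       kb_label = NA_character_, stringsAsFactors = FALSE)
    cl <- cluster_structure(d, muts)
    if (nrow(cl) == 0L) next
    expect_false(anyDuplicated(cl$residue) > 0)
  }
})

test_that("shrinking the radius never grows a cluster", {
  set.seed(15)
  d <- random_structure(12, box = 8)
  muts <- data.frame(residue = 1:12, mutation = paste0("M", 1:12),
                     recurrence = sample(1:5, 12, replace = TRUE),
                     kb_label = NA_character_, stringsAsFactors = FALSE)
  big <- cluster_structure(d, muts, radius_limit = 5)
  small <- cluster_structure(d, muts, radius_limit = 3)
  if (nrow(big) > 0L && nrow(small) > 0L) {
    # the generation-0 cluster containing the most recurrent residue
    top_big <- big[big$cluster_id == big$cluster_id[1], ]
    top_small <- small[small$cluster_id == small$cluster_id[1], ]
    expect_lte(nrow(top_small), nrow(top_big))
  }
})

test_that("planted hotspots within 4 A recover as one cluster", {
  cfg <- sim_config(seed = 31)
  st <- simulate_structure(cfg)
  hot <- st$truth$hotspots[[1]]
  muts <- data.frame(residue = sort(unique(c(st$distances$res_i,
                                             st$distances$res_j))),
                     stringsAsFactors = FALSE)
  muts$mutation <- paste0("M", muts$residue)
  muts$recurrence <- 1
  muts$recurrence[muts$residue == hot[1]] <- 10
  muts$kb_label <- NA_character_
  cl <- cluster_structure(st$distances, muts)
  expect_equal(sort(unique(cl$residue)), sort(hot))
  expect_equal(length(unique(cl$cluster_id)), 1L)
})

test_that("label propagation marks putative members and guards overlaps", {
  mk_cluster <- function(id, residues, labels, gene = "BRAF",
                         drugs = NA_character_) {
    data.frame(cluster_id = id, structure_id = "S", gene = gene,
               generation = 0L, residue = residues,
               mutation = paste0("M", residues), recurrence = 1,
               kb_label = labels, drug = drugs,
               centroid_flag = seq_along(residues) == 1,
               dist_to_centroid_A = 0, stringsAsFactors = FALSE)
  }
  # sensitive cluster: uncatalogued members become putative_sensitive
  cl1 <- mk_cluster("c1", c(600L, 601L, 604L),
                    c("sensitive", NA, NA),
                    drugs = c("dabrafenib", NA, NA))
  out1 <- propagate_labels(cl1)
  expect_setequal(out1$residue, c(601L, 604L))
  expect_true(all(out1$putative_label == "putative_sensitive"))
  expect_true(all(out1$linked_drug == "dabrafenib"))
  # resistant cluster disjoint from sensitive ones yields putative_resistant
  cl2 <- rbind(cl1, mk_cluster("c2", c(29L, 18L, 31L),
                               c("resistant", NA, NA), gene = "RAC1"))
  out2 <- propagate_labels(cl2)
  res <- out2[out2$putative_label == "putative_resistant", ]
  expect_setequal(res$residue, c(18L, 31L))
  # overlapping resistant cluster is excluded
  cl3 <- rbind(cl1, mk_cluster("c3", c(600L, 610L),
                               c("resistant", NA)))
  out3 <- suppressWarnings(propagate_labels(cl3))
  expect_false(any(out3$putative_label == "putative_resistant"))
  # a cluster with no known member yields nothing
  cl4 <- mk_cluster("c4", c(10L, 11L), c(NA, NA))
  expect_equal(nrow(propagate_labels(cl4)), 0L)
})

test_that("putative mutations become tumor-level calls at the hotspot3d tier", {
  putative <- data.frame(gene = "BRAF", structure_id = "S",
                         cluster_id = "c1", residue = 601L,
                         mutation = "K601E",
                         putative_label = "putative_sensitive",
                         linked_drug = "dabrafenib",
                         stringsAsFactors = FALSE)
  records <- rbind(mut_record("S1", "BRAF", "K601E", ct = "SKCM"),
                   mut_record("S2", "BRAF", "V600E", ct = "SKCM"))
  calls <- putative_druggability_calls(putative, records)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$sample_id, "S1")
  expect_equal(calls$data_level, "cluster_putative")
  expect_equal(calls$chosen_evidence, "hotspot3d")
})
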