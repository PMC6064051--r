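braf_kb <- kb_table(
  kb_entry("BRAF", "missense_exact", "V600E", "SKCM", "sensitive",
           "fda_approved", "dabrafenib"),
  kb_entry("BRAF", "missense_exact", "V600E", "THCA", "sensitive",
           "clinical_trial", "vemurafenib"),
  kb_entry("BRAF", "missense_position", "V600", "SKCM", "sensitive",
           "clinical_trial", "trametinib"),
  kb_entry("EGFR", "aa_range", "729-761:inframe_del", "LUAD", "sensitive",
           "fda_approved", "erlotinib"),
  kb_entry("RAC1", "missense_exact", "P29S", "SKCM", "resistant",
           "preclinical", "dabrafenib"),
  kb_entry("RAC1", "missense_exact", "P29S", "SKCM", "sensitive",
           "preclinical", "hypothetical"))

test_that("matching covers exact, ambiguous-position and range routes", {
  # ambiguous-position: V600 matches V600K (reference aa + position agree)
  hit <- match_mutation(mut_record("S1", "BRAF", "V600K", ct = "SKCM"),
                        braf_kb)
  expect_true(3L %in% hit)
  expect_false(any(c(1L, 2L) %in% hit))  # V600E exact does not match V600K
  # but not A600K (reference amino acid differs)
  expect_length(match_mutation(mut_record("S1", "BRAF", "A600K"), braf_kb),
                0L)
  # range: deletion starting inside [729, 761]
  hit2 <- match_mutation(mut_record("S2", "EGFR", "E746_A750del",
                                    cls = "inframe_del"), braf_kb)
  expect_equal(hit2, 4L)
  # start codon outside the range: no hit
  expect_length(match_mutation(mut_record("S2", "EGFR", "E770_A774del",
                                          cls = "inframe_del"), braf_kb),
                0L)
  # gene mismatch: no hit
  expect_length(match_mutation(mut_record("S3", "KRAS", "V600E"), braf_kb),
                0L)
  # V600E matches both the exact entries and the ambiguous V600 entry
  hit3 <- match_mutation(mut_record("S4", "BRAF", "V600E"), braf_kb)
  expect_setequal(hit3, c(1L, 2L, 3L))
})

test_that("call resolution applies specificity and evidence rules", {
  rec <- mut_record("S1", "BRAF", "V600E", ct = "SKCM")
  m <- match_mutation(rec, braf_kb)
  call <- resolve_call(rec, m, braf_kb, "SKCM")
  expect_equal(call$specificity, "cancer_type_specific")
  expect_equal(call$chosen_evidence, "fda_approved")
  expect_equal(call$chosen_drug, "dabrafenib")
  # THCA borrows the globally maximal evidence but is off-label
  rec2 <- mut_record("S2", "BRAF", "V600E", ct = "THCA")
  call2 <- resolve_call(rec2, match_mutation(rec2, braf_kb), braf_kb, "THCA")
  expect_equal(call2$specificity, "non_specific")
  expect_equal(call2$chosen_evidence, "fda_approved")
  # sensitive wins over resistant for the same variant
  rec3 <- mut_record("S3", "RAC1", "P29S", ct = "SKCM")
  call3 <- resolve_call(rec3, match_mutation(rec3, braf_kb), braf_kb, "SKCM")
  expect_equal(call3$effect, "sensitive")
  expect_equal(call3$chosen_drug, "hypothetical")
})

test_that("equal top evidence picks the alphabetically first drug", {
  kb <- kb_table(
    kb_entry("KRAS", "missense_exact", "G12D", "CT1", "sensitive",
             "preclinical", "zeta-drug"),
    kb_entry("KRAS", "missense_exact", "G12D", "CT2", "sensitive",
             "preclinical", "alpha-drug"))
  rec <- mut_record("S1", "KRAS", "G12D", ct = "CT3")
  call <- resolve_call(rec, match_mutation(rec, kb), kb, "CT3")
  expect_equal(call$chosen_drug, "alpha-drug")
  # and both entries stay on the call
  expect_equal(call$all_matches, "1;2")
})

test_that("tier summary counts each sample once at its best tier", {
  cohort <- data.frame(sample_id = sprintf("S%02d", 1:10),
                       cancer_type = "SKCM", stringsAsFactors = FALSE)
  calls <- rbind(
    druggability_call("S01", "BRAF", "BRAF:V600E",
                      specificity = "cancer_type_specific", ct = "SKCM"),
    druggability_call("S02", "BRAF", "BRAF:V600E",
                      specificity = "cancer_type_specific", ct = "SKCM"),
    # S02 also has a preclinical call; must not double-count
    druggability_call("S02", "KRAS", "KRAS:G12D",
                      evidence = "preclinical", ct = "SKCM"))
  tab <- summarize_mutation_druggability(calls, cohort)
  spec_fda <- tab[tab$setting == "specific" & tab$tier == "fda_approved", ]
  expect_equal(spec_fda$cumulative_fraction, 0.20)
  spec_pre <- tab[tab$setting == "specific" & tab$tier == "preclinical", ]
  expect_equal(spec_pre$cumulative_fraction, 0.20)
  nons_pre <- tab[tab$setting == "non_specific" & tab$tier == "preclinical", ]
  expect_equal(nons_pre$cumulative_fraction, 0.20)
})

test_that("cumulative tier fractions nest and non-specific dominates", {
  set.seed(5)
  kb <- random_kb(25)
  records <- random_records(150)
  calls <- annotate_cohort(records, kb)
  cohort <- unique(records[, c("sample_id", "cancer_type")])
  tab <- summarize_mutation_druggability(calls, cohort)
  for (ct in unique(tab$cancer_type)) {
    for (s in c("specific", "non_specific")) {
      v <- tab$cumulative_fraction[tab$cancer_type == ct &
                                     tab$setting == s]
      expect_true(all(diff(v) >= 0))  # fda -> preclinical grows
    }
    spec <- tab$cumulative_fraction[tab$cancer_type == ct &
                                      tab$setting == "specific"]
    nons <- tab$cumulative_fraction[tab$cancer_type == ct &
                                      tab$setting == "non_specific"]
    expect_true(all(nons >= spec))
  }
})

test_that("hash-based matching agrees with the brute-force oracle", {
  set.seed(99)
  for (rep in 1:20) {
    kb <- random_kb(sample(5:30, 1))
    records <- random_records(sample(20:100, 1))
    pk <- oracle_parse_kb(kb)
    index <- druggable:::build_kb_index(kb)
    for (i in seq_len(nrow(records))) {
      rec <- records[i, , drop = FALSE]
      got <- match_mutation(rec, kb, index)
      want <- oracle_match(rec, pk)
      expect_equal(got, sort(want))
      if (length(want) > 0L) {
        call <- resolve_call(rec, got, kb, rec$cancer_type)
        want_call <- oracle_resolve(want, pk, rec$cancer_type)
        expect_equal(call$effect, want_call$effect)
        expect_equal(call$chosen_drug, want_call$chosen_drug)
        expect_equal(call$chosen_evidence, want_call$chosen_evidence)
        expect_equal(call$specificity, want_call$specificity)
      }
    }
  }
})

test_that("resolution is invariant to knowledgebase row permutation", {
  set.seed(7)
  kb <- random_kb(20)
  records <- random_records(60)
  calls1 <- annotate_cohort(records, kb)
  perm <- sample(nrow(kb))
  kb2 <- kb[perm, , drop = FALSE]
  kb2$entry_id <- seq_len(nrow(kb2))
  calls2 <- annotate_cohort(records, kb2)
  cols <- c("sample_id", "variant_key", "effect", "specificity",
            "chosen_drug", "chosen_evidence")
  expect_equal(calls1[, cols], calls2[, cols])
})
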