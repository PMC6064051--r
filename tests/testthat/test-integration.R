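int_kb <- kb_table(
  kb_entry("BRAF", "missense_exact", "V600E", "SKCM", "sensitive",
           "fda_approved", "dabrafenib", cls = "B-Raf inhibitor"),
  kb_entry("AKT3", "expression_high", "", "UNSPECIFIED", "sensitive",
           "preclinical", "ipatasertib", cls = "AKT inhibitor"),
  kb_entry("ESR1", "expression_high", "", "BRCA", "sensitive",
           "fda_approved", "tamoxifen", cls = "Hormone therapy"),
  kb_entry("PGR", "expression_high", "", "BRCA", "sensitive",
           "fda_approved", "tamoxifen", cls = "Hormone therapy"),
  kb_entry("RAC1", "missense_exact", "P29S", "SKCM", "resistant",
           "preclinical", "dabrafenib", cls = "B-Raf inhibitor"))

ten_classes <- c("B-Raf inhibitor", "AKT inhibitor", "Hormone therapy",
                 "EGFR inhibitor", "CDK inhibitor", "MEK inhibitor",
                 "PI3K inhibitor", "HER2 inhibitor", "KIT inhibitor",
                 "MDM2 inhibitor")

simple_traits <- function(ids, ct = "SKCM") {
  data.frame(sample_id = ids, cancer_type = ct, sex = "MALE",
             race = "WHITE", stringsAsFactors = FALSE)
}

test_that("outlier calls resolve to expression druggability calls", {
  oc <- data.frame(sample_id = "S1", feature = "ESR1", level = "mrna",
                   x = 10, q1 = 1, q3 = 2, iqr = 1, score = 8,
                   direction = "high", is_outlier = TRUE,
                   stringsAsFactors = FALSE)
  calls <- annotate_outliers(oc, int_kb, simple_traits("S1", "BRCA"))
  expect_equal(calls$data_level, "mrna")
  expect_equal(calls$effect, "sensitive")
  expect_equal(calls$chosen_drug, "tamoxifen")
  expect_equal(calls$specificity, "cancer_type_specific")
  # same outlier in another cancer type is off-label
  calls2 <- annotate_outliers(oc, int_kb, simple_traits("S1", "LUAD"))
  expect_equal(calls2$specificity, "non_specific")
  # phosphosite features resolve through the parent gene
  oc3 <- oc
  oc3$feature <- "ESR1:pS118"
  oc3$level <- "phosphoprotein"
  calls3 <- annotate_outliers(oc3, int_kb, simple_traits("S1", "BRCA"))
  expect_equal(calls3$gene, "ESR1")
  expect_equal(calls3$data_level, "phosphoprotein")
})

test_that("profiles count druggable levels per sample", {
  calls <- rbind(
    druggability_call("S1", "BRAF", "BRAF:V600E", "mutation", ct = "SKCM",
                      drug = "dabrafenib"),
    druggability_call("S1", "AKT3", "AKT3:high", "mrna", ct = "SKCM",
                      drug = "ipatasertib", evidence = "preclinical"),
    druggability_call("S2", "RAC1", "RAC1:P29S", "mutation",
                      effect = "resistant", ct = "SKCM",
                      drug = "dabrafenib"))
  ids <- c("S1", "S2", "S3")
  profiles <- build_profiles(
    calls, profiled = list(mutation = ids, mrna = ids, protein = ids),
    traits = simple_traits(ids))
  expect_equal(nrow(profiles), 3L)
  s1 <- profiles[profiles$sample_id == "S1", ]
  expect_true(s1$druggable_mutation && s1$druggable_mrna)
  expect_equal(s1$n_druggable_levels, 2)
  # resistant-only sample has no druggable level
  s2 <- profiles[profiles$sample_id == "S2", ]
  expect_equal(s2$n_druggable_levels, 0)
  # incomplete profiling excludes a sample from the denominator
  profiles2 <- build_profiles(
    calls, profiled = list(mutation = ids, mrna = ids, protein = c("S1")),
    traits = simple_traits(ids))
  expect_equal(profiles2$sample_id, "S1")
})

test_that("multi-omics fraction counts >= 2 druggable levels", {
  ids <- sprintf("S%02d", 1:10)
  calls <- rbind(
    do.call(rbind, lapply(ids[1:4], function(s) rbind(
      druggability_call(s, "BRAF", "BRAF:V600E", "mutation", ct = "SKCM",
                        drug = "dabrafenib"),
      druggability_call(s, "AKT3", "AKT3:high", "mrna", ct = "SKCM",
                        drug = "ipatasertib")))),
    do.call(rbind, lapply(ids[5:7], function(s)
      druggability_call(s, "BRAF", "BRAF:V600E", "mutation", ct = "SKCM",
                        drug = "dabrafenib"))))
  profiles <- build_profiles(
    calls, profiled = list(mutation = ids, mrna = ids, protein = ids),
    traits = simple_traits(ids))
  mo <- multiomics_fraction(profiles)
  expect_equal(mo$fraction, 0.40)
  expect_equal(mo$n_total, 10L)
  # an all-mutation cohort has fraction zero
  calls2 <- calls[calls$data_level == "mutation", ]
  mo2 <- multiomics_fraction(build_profiles(
    calls2, profiled = list(mutation = ids, mrna = ids, protein = ids),
    traits = simple_traits(ids)))
  expect_equal(mo2$fraction, 0)
  expect_error(multiomics_fraction(build_profiles(
    calls, profiled = list(mutation = character(0), mrna = character(0),
                           protein = character(0)),
    traits = simple_traits(ids))), "denominator")
})

test_that("sector tables carry cross-links and within-class links", {
  calls <- rbind(
    # S1: ESR1 and PGR mRNA outliers -> one within-class link
    druggability_call("S1", "ESR1", "ESR1:high", "mrna", ct = "BRCA",
                      drug = "tamoxifen"),
    druggability_call("S1", "PGR", "PGR:high", "mrna", ct = "BRCA",
                      drug = "tamoxifen"),
    # S2: biomarkers in two classes -> one cross-link
    druggability_call("S2", "BRAF", "BRAF:V600E", "mutation", ct = "SKCM",
                      drug = "dabrafenib"),
    druggability_call("S2", "AKT3", "AKT3:high", "mrna", ct = "SKCM",
                      drug = "ipatasertib"),
    # S3: a single biomarker -> no links
    druggability_call("S3", "BRAF", "BRAF:V600E", "mutation", ct = "SKCM",
                      drug = "dabrafenib"))
  out <- drug_class_sectors(calls, int_kb, ten_classes)
  expect_equal(nrow(out$within_links), 1L)
  expect_equal(out$within_links$sample_id, "S1")
  expect_equal(nrow(out$cross_links), 1L)
  expect_equal(out$cross_links$sample_id, "S2")
  expect_false("S3" %in% out$cross_links$sample_id)
  expect_error(drug_class_sectors(calls, int_kb, ten_classes[1:9]),
               "viz_classes")
})

test_that("co-occurrence flags resistance pairs and combination candidates", {
  calls <- rbind(
    druggability_call("S1", "BRAF", "BRAF:V600E", "mutation", ct = "SKCM",
                      drug = "dabrafenib"),
    druggability_call("S1", "RAC1", "RAC1:P29S", "mutation",
                      effect = "resistant", ct = "SKCM",
                      drug = "dabrafenib"),
    druggability_call("S2", "BRAF", "BRAF:V600E", "mutation", ct = "SKCM",
                      drug = "dabrafenib"),
    druggability_call("S2", "ESR1", "ESR1:high", "mrna", ct = "SKCM",
                      drug = "tamoxifen"),
    druggability_call("S3", "BRAF", "BRAF:V600E", "mutation", ct = "SKCM",
                      drug = "dabrafenib"))
  out <- cooccurrence_report(calls, int_kb)
  expect_equal(out$flag[out$sample_id == "S1"], "sensitive_resistant")
  expect_equal(out$flag[out$sample_id == "S2"], "combination_candidate")
  expect_false("S3" %in% out$sample_id)
})

test_that("cumulative tier curves match planted tier fractions", {
  n <- 100
  ids <- sprintf("S%03d", 1:n)
  cohort <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  tiers <- c(fda_approved = 5, clinical_trial = 10, case_report = 15,
             preclinical = 20, hotspot3d = 25)
  calls <- NULL
  start <- 1
  for (tier in names(tiers)) {
    take <- ids[start:(start + tiers[[tier]] - 1)]
    calls <- rbind(calls, do.call(rbind, lapply(take, function(s)
      druggability_call(s, "G", "G:x",
                        data_level = if (tier == "hotspot3d")
                          "cluster_putative" else "mutation",
                        evidence = tier))))
    start <- start + tiers[[tier]]
  }
  out <- cumulative_tier_summary(calls, cohort)
  nons <- out[out$setting == "non_specific", ]
  expect_equal(nons$cumulative_fraction,
               c(0.05, 0.15, 0.30, 0.50, 0.75))
  expect_true(all(diff(nons$cumulative_fraction) >= 0))
  # no calls -> all zeros
  out0 <- cumulative_tier_summary(calls[0, ], cohort)
  expect_true(all(out0$cumulative_fraction == 0))
})
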