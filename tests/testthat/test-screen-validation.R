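test_that("drug mapping matches by name, synonym, and target", {
  screen_drugs <- data.frame(
    drug_id = c("D1", "D2", "D3"),
    drug_name = c("Dabrafenib", "compound-x", "nutlin-3a"),
    synonyms = c("GSK2118436", "erlotinib;OSI-774", ""),
    targets = c("BRAF", "EGFR", "MDM2"), stringsAsFactors = FALSE)
  out <- map_drugs(c("dabrafenib", "erlotinib", "unknownib"), screen_drugs,
                   kb_targets = data.frame(drug = "unknownib",
                                           target = "NOGENE",
                                           stringsAsFactors = FALSE))
  expect_equal(out$map$drug_id[out$map$kb_drug == "dabrafenib"], "D1")
  expect_equal(out$map$drug_id[out$map$kb_drug == "erlotinib"], "D2")
  expect_equal(out$unmapped, "unknownib")
  # target-based match
  out2 <- map_drugs("some-braf-inhibitor", screen_drugs,
                    kb_targets = data.frame(drug = "some-braf-inhibitor",
                                            target = "BRAF",
                                            stringsAsFactors = FALSE))
  expect_equal(out2$map$matched_by, "target")
})

test_that("Mann-Whitney p matches exact enumeration on small groups", {
  # {1,2} vs {3,4}: U = 0, exact two-sided p = 1/3
  expect_equal(mw_exact_p(c(1, 2), c(3, 4)), 1 / 3)
  wt <- stats::wilcox.test(c(1, 2), c(3, 4), exact = TRUE)
  expect_equal(wt$p.value, 1 / 3)
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    x <- stats::runif(n); y <- stats::runif(m)
    expect_equal(stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 mw_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("screen test recovers a planted LN(IC50) shift", {
  cfg <- sim_config(seed = 51)
  sc <- simulate_screen(cfg)
  kb <- cfg$kb
  res <- suppressWarnings(
    mutation_sensitivity_test(sc$screen, kb, sc$cl_maf, sc$drug_map))
  expect_lt(res$global$p_value, 1e-6)
  expect_gt(res$global$n, 0)
  # every planted (variant, drug) combination with >= 5 lines is significant
  planted <- merge(res$per_combination, sc$truth$delta,
                   by = c("variant_key", "drug_id"))
  expect_gt(nrow(planted), 0)
  expect_true(all(planted$p_value < 0.05))
  expect_true(all(res$per_combination$n >= 5))
})

test_that("specific setting restricts to tissue-matched lines", {
  cfg <- sim_config(seed = 52)
  sc <- simulate_screen(cfg)
  spec <- suppressWarnings(
    mutation_sensitivity_test(sc$screen, cfg$kb, sc$cl_maf, sc$drug_map,
                              setting = "specific"))
  nons <- suppressWarnings(
    mutation_sensitivity_test(sc$screen, cfg$kb, sc$cl_maf, sc$drug_map,
                              setting = "non_specific"))
  expect_lte(spec$global$n, nons$global$n)
})

test_that("OLS matches the closed-form normal equations", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 30
    x <- stats::rnorm(n)
    y <- -0.8 * x + stats::rnorm(n, 0, 0.1)
    fit <- stats::lm(y ~ x)
    b_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a_hat <- mean(y) - b_hat * mean(x)
    expect_equal(unname(coef(fit)["x"]), b_hat, tolerance = 1e-10)
    expect_equal(unname(coef(fit)["(Intercept)"]), a_hat, tolerance = 1e-10)
  }
})

test_that("regressions recover the planted slope and validate genes", {
  cfg <- sim_config(seed = 53)
  sc <- simulate_screen(cfg)
  reg <- expression_sensitivity_regression(sc$screen, sc$cl_expr,
                                           sc$probe_map, cfg$kb,
                                           sc$drug_map)
  expect_true(all(reg$regressions$n >= 5))
  planted <- merge(reg$regressions, sc$truth$beta,
                   by = c("gene", "drug_id"))
  expect_gt(nrow(planted), 0)
  # causal probes recover beta closely; the correlated second probe is
  # attenuated but still negative and significant
  causal <- planted[grepl("_1$", planted$probe_id), ]
  expect_true(all(abs(causal$slope - causal$beta) < 0.15))
  expect_true(all(planted$significant))
  expect_true(all(unique(planted$gene) %in% reg$validated_genes))
})

test_that("combinations below five lines are skipped", {
  screen <- data.frame(cell_line_id = sprintf("C%d", 1:4),
                       tissue_type = "SKCM", drug_id = "D1",
                       ln_ic50 = stats::rnorm(4), stringsAsFactors = FALSE)
  expr <- matrix(stats::rnorm(4), nrow = 1,
                 dimnames = list("P_ERBB2_1", sprintf("C%d", 1:4)))
  kb <- kb_table(kb_entry("ERBB2", "expression_high", "", "BRCA",
                          "sensitive", "fda_approved", "trastuzumab"))
  dm <- data.frame(kb_drug = "trastuzumab", drug_id = "D1",
                   matched_by = "name", stringsAsFactors = FALSE)
  pm <- data.frame(probe_id = "P_ERBB2_1", gene = "ERBB2",
                   stringsAsFactors = FALSE)
  reg <- expression_sensitivity_regression(screen, expr, pm, kb, dm)
  expect_equal(nrow(reg$regressions), 0L)
  expect_length(reg$validated_genes, 0L)
})

test_that("null regressions rarely reach significance and never validate on positive slopes", {
  set.seed(43)
  sig <- logical(200)
  for (rep in 1:200) {
    x <- stats::rnorm(30)
    y <- stats::rnorm(30)  # independent of x
    sm <- summary(stats::lm(y ~ x))$coefficients
    sig[rep] <- sm["x", "Pr(>|t|)"] < 0.05 && sm["x", "Estimate"] < 0
  }
  # one-sided halving of the nominal 5%: expect around 2.5%
  expect_lt(mean(sig), 0.08)
})
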