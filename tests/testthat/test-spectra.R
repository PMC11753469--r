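genes <- lps_gene_catalogue()

test_that("causal-gene assignment follows severity then catalogue order", {
  expect_equal(assign_causal_gene(c("galE", "hldE"), genes), "hldE")
  expect_equal(assign_causal_gene("waaO", genes), "waaO")
  # tie within a class: catalogue-earlier gene, regardless of input order
  expect_equal(assign_causal_gene(c("waaW", "waaT"), genes), "waaW")
  expect_equal(assign_causal_gene(c("waaT", "waaW"), genes), "waaW")
  # regulatory beats rough, deep-rough beats regulatory
  expect_equal(assign_causal_gene(c("galE", "rfaH"), genes), "rfaH")
  expect_equal(assign_causal_gene(c("rfaH", "waaC"), genes), "waaC")
  # uncatalogued genes rank last; all-unknown returns the first listed
  expect_equal(assign_causal_gene(c("zzz", "yajC"), genes), "yajC")
  expect_equal(assign_causal_gene(c("abc", "xyz"), genes), "abc")
  expect_equal(gene_class("abc", genes), "non_lps")
  expect_error(assign_causal_gene(character(0), genes), "non-empty")
})

test_that("spectra are zero-filled over the catalogue and normalized", {
  mut <- data.frame(
    isolate_id = c("i1", "i2", "i3"),
    environment = c("phage", "phage", "phage_CL2"),
    mutated_genes = c("waaC", "waaC;galE", "waaT")
  )
  sp <- mutant_spectrum(mut, "phage", genes)
  expect_equal(unname(sp$counts["waaC"]), 2L)
  expect_equal(sp$n_isolates, 2L)
  expect_equal(unname(sp$proportions["waaC"]), 1)
  expect_equal(sum(sp$proportions), 1)
  expect_equal(length(sp$counts), nrow(genes))
  expect_equal(unname(sp$class_proportions["deep_rough"]), 1)
  expect_error(mutant_spectrum(mut, "no_env", genes), "no isolates")
})

test_that("bootstrap SDs match the exact two-isolate enumeration", {
  mut <- data.frame(isolate_id = c("a", "b"), environment = "e",
                    causal_gene = c("waaC", "galE"))
  sp <- mutant_spectrum(mut, "e", genes)
  # no pseudo-counts: 4 equiprobable resamples give proportion SD
  # sqrt(p(1-p)/2) with p = 1/2, i.e. ~0.3536, approached as n_boot grows
  boot <- bootstrap_spectrum(sp, candidate_genes = character(0),
                             n_boot = 40000, pseudo_count = 0, seed = 1,
                             catalogue = genes)
  expect_equal(unname(boot$sd_gene["waaC"]), sqrt(0.25 / 2), tolerance = 0.02)
  # a pool made of a single gene has zero spread
  mut1 <- data.frame(isolate_id = "a", environment = "e", causal_gene = "waaC")
  sp1 <- mutant_spectrum(mut1, "e", genes)
  b1 <- bootstrap_spectrum(sp1, character(0), n_boot = 50,
                           pseudo_count = 0, seed = 2, catalogue = genes)
  expect_equal(unname(b1$sd_gene["waaC"]), 0)
  # identical seeds reproduce identical SDs; different seeds differ
  b2 <- bootstrap_spectrum(sp, c("waaP", "gmhB"), n_boot = 100,
                           pseudo_count = 1, seed = 33, catalogue = genes)
  b3 <- bootstrap_spectrum(sp, c("waaP", "gmhB"), n_boot = 100,
                           pseudo_count = 1, seed = 33, catalogue = genes)
  expect_identical(b2$sd_gene, b3$sd_gene)
  expect_equal(b2$pool_size, 4)   # 2 observed + 2 pseudo
})

test_that("bootstrap SDs shrink like one over the square root of pool size", {
  sds <- vapply(c(10, 40, 160), function(n) {
    mut <- data.frame(isolate_id = as.character(seq_len(n)),
                      environment = "e",
                      causal_gene = rep(c("waaC", "galE"), n / 2))
    sp <- mutant_spectrum(mut, "e", genes)
    b <- bootstrap_spectrum(sp, character(0), n_boot = 4000,
                            pseudo_count = 0, seed = n, catalogue = genes)
    unname(b$sd_gene["waaC"])
  }, numeric(1))
  expect_equal(sds[1] / sds[2], 2, tolerance = 0.15)
  expect_equal(sds[2] / sds[3], 2, tolerance = 0.15)
})

test_that("chi-square GOF matches the textbook computation", {
  surv <- table1_survival()
  # 2-category toy: observed (8, 2) vs equal expectation -> X2 = 3.6
  mut <- data.frame(
    isolate_id = as.character(1:10), environment = "e",
    causal_gene = rep(c("waaC", "galE"), c(8, 2)))
  sp <- mutant_spectrum(mut, "e", genes)
  two <- genes[genes$gene %in% c("waaC", "galE"), ]
  pred <- predicted_distributions(
    .mock_weights(c(waaC = 1, galE = 1)), two)
  g <- gof_chisq(sp, pred, "gene_wise", genes)
  expect_equal(g$statistic, 3.6, tolerance = 1e-10)
  expect_equal(g$p_value, pchisq(3.6, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # agreement with the independent oracle and with stats::chisq.test
  orc <- oracle_pearson(c(8, 2), c(0.5, 0.5))
  expect_equal(g$statistic, orc$statistic, tolerance = 1e-10)
  ct <- suppressWarnings(chisq.test(c(8, 2), p = c(0.5, 0.5)))
  expect_equal(g$statistic, unname(ct$statistic), tolerance = 1e-10)
  expect_equal(g$p_value, ct$p.value, tolerance = 1e-10)

  # observed exactly proportional to expectation -> statistic 0, p = 1
  mut2 <- data.frame(isolate_id = as.character(1:4), environment = "e",
                     causal_gene = rep(c("waaC", "galE"), each = 2))
  sp2 <- mutant_spectrum(mut2, "e", genes)
  g2 <- gof_chisq(sp2, pred, "gene_wise", genes)
  expect_equal(g2$statistic, 0)
  expect_equal(g2$p_value, 1)

  # a category observed but with zero expectation demands the added genes
  pred_m1 <- predicted_distributions(
    model1_weights(genes, surv, "phage"), genes)
  mut3 <- data.frame(isolate_id = "x", environment = "e",
                     causal_gene = "hldD")
  sp3 <- mutant_spectrum(mut3, "e", genes)
  expect_error(gof_chisq(sp3, pred_m1, "gene_wise", genes), "added-genes")
  # the added-genes catalogue resolves it
  genes15 <- lps_gene_catalogue(added_genes = TRUE)
  pred15 <- predicted_distributions(
    model1_weights(genes15, surv, "phage"), genes15)
  sp15 <- mutant_spectrum(mut3, "e", genes15)
  g15 <- gof_chisq(sp15, pred15, "gene_wise", genes15)
  expect_true(is.finite(g15$statistic))
})

test_that("lps-type GOF aggregates classes before testing", {
  surv <- table1_survival()
  mut <- data.frame(
    isolate_id = as.character(1:50), environment = "e",
    causal_gene = rep(c("waaC", "hldE", "galE", "rfaH"), c(25, 18, 5, 2)))
  sp <- mutant_spectrum(mut, "e", genes)
  pred <- predicted_distributions(model1_weights(genes, surv, "phage"), genes)
  g <- gof_chisq(sp, pred, "lps_type", genes)
  obs <- c(rough = 5, deep_rough = 43, regulatory = 2)
  orc <- oracle_pearson(obs, pred$lps_type_proportions[names(obs)])
  expect_equal(g$statistic, orc$statistic, tolerance = 1e-10)
  expect_equal(g$p_value, orc$p_value, tolerance = 1e-10)
})
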