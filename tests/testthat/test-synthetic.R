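test_that("cohort generation is a pure function of its configuration", {
  cfg <- cohort_config(n_genes = 200, n_de = 10, n_control = 15, n_case = 15,
                       n_batches = 2, batch_shift_sd = 0.5, dup_rate = 0.1,
                       seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth$de_genes, b$truth$de_genes)
  # different seed changes the draw
  c2 <- generate_cohort(cohort_config(n_genes = 200, n_de = 10,
                                      n_control = 15, n_case = 15, seed = 8))
  expect_false(identical(a$expr[1:5, 1:5], c2$expr[1:5, 1:5]))
})

test_that("cohort structure matches the configuration", {
  cfg <- cohort_config(n_genes = 300, n_de = 12, n_control = 20, n_case = 24,
                       n_batches = 2, dup_rate = 0.1, seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$expr), 300 + 30)           # duplicates appended
  expect_equal(ncol(co$expr), 44)
  expect_equal(length(unique(rownames(co$expr))), 300)
  expect_equal(nrow(co$truth$de_genes), 12)
  expect_true(all(co$truth$de_genes$gene_id %in% rownames(co$expr)))
  # batches balanced across classes
  tab <- table(co$labels$batch, co$labels$class)
  expect_true(all(abs(tab[, "control"] / 20 - tab[, "case"] / 24) < 0.1))
})

test_that("a null cohort plants no class-mean differences", {
  co <- generate_cohort(cohort_config(n_genes = 500, n_de = 0,
                                      n_control = 10, n_case = 10, seed = 2))
  expect_equal(nrow(co$truth$de_genes), 0)
})

test_that("empirical logFC of planted genes tracks the planted values", {
  co <- generate_cohort(cohort_config(n_genes = 2000, n_de = 40,
                                      logfc_range = c(0.7, 2.5),
                                      n_control = 60, n_case = 60,
                                      noise_sd = 1, seed = 1))
  # oracle: sample logFC computed directly from the emitted matrix
  obs <- log_fold_change(co$expr, co$labels)[co$truth$de_genes$gene_id]
  expect_gt(cor(obs, co$truth$de_genes$logfc), 0.9)
})

test_that("planted logFC converges to its value at large n", {
  co <- generate_cohort(cohort_config(n_genes = 2000, n_de = 40,
                                      n_control = 200, n_case = 200,
                                      noise_sd = 1, seed = 11))
  obs <- log_fold_change(co$expr, co$labels)[co$truth$de_genes$gene_id]
  dev <- obs - co$truth$de_genes$logfc
  # estimator SD is noise_sd * sqrt(2/200) = 0.1 per gene: check the
  # average deviation and the absence of systematic bias at that scale
  expect_lt(mean(abs(dev)), 0.1)
  expect_lt(abs(mean(dev)), 0.05)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(n_genes = 0), "n_genes")
  expect_error(cohort_config(n_de = 50, n_genes = 10), "n_de")
  expect_error(cohort_config(logfc_range = c(0, 1)), "logfc_range")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(dup_rate = 1.5), "dup_rate")
  expect_error(cohort_config(batch_props = c(1, 1), n_batches = 3),
               "batch_props")
})

test_that("mixtures are exact linear combinations of signature columns", {
  sig <- synthetic_signature(n_genes = 60, cell_types = c("a", "b", "c"),
                             seed = 1)
  # unit fraction on one type reproduces that signature column
  f <- matrix(c(0, 1, 0), 3, 1)
  mix <- generate_mixture(sig, 1, noise_sd = 0, seed = 1, fractions = f)
  expect_equal(unname(mix$expr[, 1]), unname(unclass(sig)[, 2]))
  # 0.3 / 0.7 combination
  f2 <- matrix(c(0.3, 0.7, 0), 3, 1)
  mix2 <- generate_mixture(sig, 1, noise_sd = 0, seed = 1, fractions = f2)
  expect_equal(unname(mix2$expr[, 1]),
               unname(0.3 * unclass(sig)[, 1] + 0.7 * unclass(sig)[, 2]))
})

test_that("mixture fractions are seeded, on the simplex, and recorded", {
  sig <- synthetic_signature(n_genes = 50, seed = 2)
  m1 <- generate_mixture(sig, 20, noise_sd = 0.1, seed = 5)
  m2 <- generate_mixture(sig, 20, noise_sd = 0.1, seed = 5)
  expect_identical(m1$truth$mixing_fractions, m2$truth$mixing_fractions)
  expect_identical(m1$expr, m2$expr)
  fr <- m1$truth$mixing_fractions
  expect_true(all(fr >= 0))
  expect_equal(unname(colSums(fr)), rep(1, 20))
  expect_error(generate_mixture(sig, 0), "n_samples")
})
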