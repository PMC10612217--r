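test_that("NNLS deconvolution recovers noiseless mixtures exactly", {
  sig <- synthetic_signature(n_genes = 80, cell_types = c("mono", "neut",
                                                          "t", "b"), seed = 1)
  # unit vector on one cell type
  f <- matrix(c(0, 0, 1, 0), 4, 1)
  mix <- generate_mixture(sig, 1, noise_sd = 0, fractions = f)
  est <- deconvolve_fractions(mix$expr, sig)
  expect_equal(unname(est$fractions[, 1]), c(0, 0, 1, 0), tolerance = 1e-6)
  # arbitrary known composition
  f2 <- matrix(c(0.3, 0.7, 0, 0), 4, 1)
  mix2 <- generate_mixture(sig, 1, noise_sd = 0, fractions = f2)
  est2 <- deconvolve_fractions(mix2$expr, sig)
  expect_equal(unname(est2$fractions[, 1]), c(0.3, 0.7, 0, 0),
               tolerance = 1e-6)
  expect_lt(est2$rmse[1], 1e-8)
})

test_that("deconvolution stays accurate under noise and on the simplex", {
  sig <- synthetic_signature(n_genes = 150, seed = 2)
  mix <- generate_mixture(sig, 50, noise_sd = 0.5, seed = 3)
  est <- deconvolve_fractions(mix$expr, sig)
  err <- abs(est$fractions - mix$truth$mixing_fractions)
  expect_lt(mean(err), 0.05)
  expect_true(all(est$fractions >= 0))
  expect_equal(unname(colSums(est$fractions)), rep(1, 50), tolerance = 1e-9)
})

test_that("nu-SVR deconvolution approximates the known composition", {
  sig <- synthetic_signature(n_genes = 100, cell_types = c("a", "b", "c"),
                             seed = 4)
  f <- matrix(c(0.2, 0.5, 0.3), 3, 5)
  mix <- generate_mixture(sig, 5, noise_sd = 0, fractions = f)
  est <- deconvolve_fractions(mix$expr, sig, method = "nu-svr")
  expect_lt(mean(abs(est$fractions - f)), 0.05)
  expect_error(deconvolve_fractions(mix$expr, sig[, 1, drop = FALSE]),
               ">= 2 cell types")
})

test_that("Spearman correlation matches the hand rank computation", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)              # monotone up
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  # Sum d^2 = 4 over n = 5: rho = 1 - 6*4/(5*24) = 0.8
  res <- spearman_cor(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(res$rho, 0.8)
  # t-approximation p-value closed form
  tt <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(res$p, 2 * pt(-abs(tt), df = 3), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  set.seed(20)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman_cor(exp(x), y)$rho, spearman_cor(x, y)$rho)
  expect_equal(spearman_cor(x, y^3 + 10)$rho,
               spearman_cor(x, sign(y) * abs(y))$rho)
  # degenerate input flagged
  expect_warning(res0 <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res0$rho))
  expect_equal(res0$p, 1)
})

test_that("exact small-sample Spearman p agrees with the reference", {
  set.seed(21)
  x <- rnorm(8); y <- rnorm(8)
  res <- spearman_cor(x, y, exact = TRUE)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(res$p, ref$p.value)
  expect_equal(res$rho, unname(ref$estimate))
})

test_that("gene-fraction correlation recovers planted relations", {
  sig <- synthetic_signature(n_genes = 120, seed = 5)
  mix <- generate_mixture(sig, 60, noise_sd = 0, seed = 6)
  fr <- mix$truth$mixing_fractions
  # a gene equal to a cell type's fraction correlates perfectly
  expr <- rbind(gene_mono = fr["monocyte", ],
                gene_rand = rnorm(60))
  colnames(expr) <- colnames(fr)
  out <- correlate_gene_fractions(expr, fr, genes = "gene_mono")
  expect_equal(out$rho[out$cell_type == "monocyte"], 1)
  expect_equal(out$cell_type[1], "monocyte")           # sorted by |rho|
})

test_that("independent genes show near-zero correlation with fractions", {
  set.seed(22)
  sig <- synthetic_signature(n_genes = 80, cell_types = c("a", "b", "c"),
                             seed = 7)
  mix <- generate_mixture(sig, 100, noise_sd = 0, seed = 8)
  fr <- mix$truth$mixing_fractions
  rhos <- replicate(100, {
    g <- rnorm(100)
    abs(spearman_cor(g, fr["a", ])$rho)
  })
  expect_lt(mean(rhos), 0.15)
})

test_that("a planted monocyte-driven gene ranks monocytes first", {
  sig <- synthetic_signature(n_genes = 100, seed = 9)
  hits <- vapply(1:20, function(rep) {
    mix <- generate_mixture(sig, 80, noise_sd = 0, seed = 100 + rep)
    fr <- mix$truth$mixing_fractions
    set.seed(200 + rep)
    g <- 2 * fr["monocyte", ] + rnorm(80, 0, 0.05)
    expr <- rbind(G = g); colnames(expr) <- colnames(fr)
    out <- correlate_gene_fractions(expr, fr)
    out$cell_type[which.max(abs(out$rho))] == "monocyte"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
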