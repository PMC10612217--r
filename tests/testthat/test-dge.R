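test_that("log fold change is the case-minus-control mean difference", {
  m <- rbind(g1 = c(1, 1, 2, 2), g2 = c(3, 3, 3, 3))
  colnames(m) <- paste0("s", 1:4)
  lab <- make_labels(m, 2)
  lfc <- log_fold_change(m, lab)
  expect_equal(unname(lfc), c(1, 0))

  set.seed(3)
  m2 <- matrix(rnorm(50 * 12), 50, 12,
               dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:12)))
  lab2 <- make_labels(m2, 5)
  oracle <- apply(m2, 1, function(v) mean(v[6:12]) - mean(v[1:5]))
  expect_equal(log_fold_change(m2, lab2), oracle, tolerance = 1e-12)
  expect_error(log_fold_change(m2, transform(lab2, class = "case")),
               "class")
})

test_that("zero prior df reduces the moderated t to the ordinary pooled t", {
  set.seed(4)
  m <- matrix(rnorm(100 * 16), 100, 16,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:16)))
  lab <- make_labels(m, 8)
  mt <- moderated_t(m, lab, d0 = 0)
  ordinary <- apply(m, 1, function(v) {
    a <- v[1:8]; b <- v[9:16]
    sp <- sqrt(((7 * var(a) + 7 * var(b)) / 14) * (1 / 8 + 1 / 8))
    (mean(b) - mean(a)) / sp
  })
  expect_equal(unname(mt$table$t), unname(ordinary), tolerance = 1e-9)
  expect_equal(mt$table$df[1], 14)
})

test_that("infinite prior df uses the prior variance for every gene", {
  set.seed(5)
  m <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:10)))
  lab <- make_labels(m, 5)
  mt <- moderated_t(m, lab, d0 = Inf)
  s0 <- mt$params$s0_sq
  expected <- mt$table$logFC / sqrt(s0 * (1 / 5 + 1 / 5))
  expect_equal(mt$table$t, expected, tolerance = 1e-12)
})

test_that("moderation hyperparameters and t match the reference EB fit", {
  skip_if_not_installed("limma")
  set.seed(9)
  G <- 300; n <- 30
  sds <- exp(rnorm(G, 0, 0.5))          # heteroscedastic genes: finite d0
  m <- matrix(rnorm(G * n, 0, rep(sds, n)), G,
              dimnames = list(sprintf("g%03d", 1:G), paste0("s", 1:n)))
  lab <- make_labels(m, 15)
  mt <- moderated_t(m, lab)
  ref <- limma::eBayes(limma::lmFit(m, stats::model.matrix(~ lab$class)))
  expect_true(is.finite(mt$params$d0))
  expect_equal(mt$params$d0, ref$df.prior, tolerance = 1e-8)
  expect_equal(mt$params$s0_sq, ref$s2.prior, tolerance = 1e-8)
  expect_equal(unname(mt$table$t), unname(ref$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(mt$table$p), unname(ref$p.value[, 2]), tolerance = 1e-8)
})

test_that("moderated p-values are calibrated on a null cohort", {
  co <- generate_cohort(cohort_config(n_genes = 2000, n_de = 0,
                                      n_control = 30, n_case = 30, seed = 3))
  mt <- moderated_t(co$expr, co$labels)
  frac <- mean(mt$table$p < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  ks <- stats::ks.test(mt$table$p, "punif")$p.value
  expect_gt(ks, 0.01)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "finite")
})

test_that("BH adjustment equals a brute-force step-up oracle", {
  set.seed(10)
  for (i in 1:100) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= 0 & adj <= 1))
  }
})

test_that("DEG selection applies strict dual thresholds and directions", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    logFC = c(0.69, -1.2, 0.8, 2.0),
                    fdr = c(0.001, 0.01, 0.05, 0.2))
  out <- select_degs(tab)
  expect_false(out$selected[1])                        # |logFC| not > 0.7
  expect_true(out$selected[2])
  expect_equal(out$direction[2], "down")
  expect_false(out$selected[3])                        # fdr not < 0.05
  expect_false(out$selected[4])
  expect_equal(out$direction[1], "ns")
  expect_error(select_degs(tab, lfc_threshold = 0), "positive")
})

test_that("DEG selection is monotone in both thresholds", {
  set.seed(11)
  tab <- data.frame(gene = sprintf("g%03d", 1:200),
                    logFC = rnorm(200, 0, 1.2), fdr = runif(200))
  base <- select_degs(tab, 0.7, 0.05)
  harder_lfc <- select_degs(tab, 1.0, 0.05)
  harder_fdr <- select_degs(tab, 0.7, 0.01)
  expect_true(all(harder_lfc$gene[harder_lfc$selected] %in%
                    base$gene[base$selected]))
  expect_true(all(harder_fdr$gene[harder_fdr$selected] %in%
                    base$gene[base$selected]))
})

test_that("planted DE genes are recovered with few false positives", {
  co <- generate_cohort(cohort_config(n_genes = 2000, n_de = 40,
                                      logfc_range = c(1.2, 2.5),
                                      n_control = 60, n_case = 60,
                                      noise_sd = 1, seed = 1))
  tab <- run_dge(co$expr, co$labels)
  hits <- tab$gene[tab$selected]
  planted <- co$truth$de_genes$gene_id
  expect_gte(mean(planted %in% hits), 0.9)
  expect_lte(length(setdiff(hits, planted)), 5)
  # direction agrees with the planted sign
  dir <- tab$direction[match(planted, tab$gene)]
  planted_dir <- ifelse(co$truth$de_genes$logfc > 0, "up", "down")
  agree <- dir[dir != "ns"] == planted_dir[dir != "ns"]
  expect_true(all(agree))
})
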