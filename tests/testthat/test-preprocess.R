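test_that("duplicate collapsing averages rows and is idempotent", {
  m <- matrix(1:8, 2, 4, dimnames = list(c("G1", "G2"), paste0("s", 1:4)))
  expect_identical(collapse_duplicates(m), m)          # no duplicates

  m2 <- rbind(G1 = c(1, 3), G1 = c(3, 5))
  colnames(m2) <- c("s1", "s2")
  out <- collapse_duplicates(m2)
  expect_equal(out, rbind(G1 = c(s1 = 2, s2 = 4)))

  # group-by-mean oracle on a larger fixture with k-fold duplications
  set.seed(1)
  base <- matrix(rnorm(10 * 6), 10, 6,
                 dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:6)))
  dups <- base[c(2, 2, 5, 5, 5, 9), ] + rnorm(36)
  big <- rbind(base, dups)
  out2 <- collapse_duplicates(big)
  expect_equal(nrow(out2), 10)
  expect_equal(rownames(out2), rownames(base))         # first-occurrence order
  for (g in unique(rownames(big))) {
    grp <- big[rownames(big) == g, , drop = FALSE]
    expect_equal(out2[g, ], colMeans(grp))
  }
  expect_identical(collapse_duplicates(out2), out2)    # idempotent
  expect_error(collapse_duplicates(matrix(nrow = 0, ncol = 0)), "empty")
})

test_that("single-batch input passes through batch adjustment unchanged", {
  co <- generate_cohort(cohort_config(n_genes = 50, n_de = 0,
                                      n_control = 8, n_case = 8, seed = 4))
  res <- combat_adjust(co$expr, co$labels)
  expect_lt(max(abs(res$adjusted - co$expr)), 1e-6)
})

test_that("batch adjustment removes planted additive offsets", {
  co <- generate_cohort(cohort_config(n_genes = 400, n_de = 0,
                                      n_control = 30, n_case = 30,
                                      n_batches = 2, batch_shift_sd = 1,
                                      seed = 6))
  res <- combat_adjust(co$expr, co$labels)
  b <- co$labels$batch
  gap <- function(m) abs(rowMeans(m[, b == "B1"]) - rowMeans(m[, b == "B2"]))
  pre <- mean(gap(co$expr))
  post <- mean(gap(res$adjusted))
  expect_lt(post, 0.1 * pre)                           # >= 90% shrinkage
  # shape, dimnames and gene order preserved
  expect_identical(dim(res$adjusted), dim(co$expr))
  expect_identical(dimnames(res$adjusted), dimnames(co$expr))
  # overall per-gene mean essentially preserved
  expect_lt(max(abs(rowMeans(res$adjusted) - rowMeans(co$expr))), 0.05)
})

test_that("batch adjustment preserves a class effect balanced across batches", {
  co <- generate_cohort(cohort_config(n_genes = 500, n_de = 25,
                                      logfc_range = c(1, 2),
                                      n_control = 40, n_case = 40,
                                      n_batches = 2, batch_shift_sd = 1,
                                      seed = 8))
  res <- combat_adjust(co$expr, co$labels)
  planted <- co$truth$de_genes$gene_id
  pre <- log_fold_change(co$expr, co$labels)[planted]
  post <- log_fold_change(res$adjusted, co$labels)[planted]
  expect_lt(max(abs(post - pre)), 0.1)
})

test_that("with no batch effects the class contrast is essentially untouched", {
  co <- generate_cohort(cohort_config(n_genes = 500, n_de = 20,
                                      n_control = 60, n_case = 60,
                                      n_batches = 2, batch_shift_sd = 0,
                                      seed = 9))
  res <- combat_adjust(co$expr, co$labels)
  pre <- log_fold_change(co$expr, co$labels)
  post <- log_fold_change(res$adjusted, co$labels)
  expect_lt(max(abs(post - pre)), 0.05)
})

test_that("batch adjustment agrees with the reference implementation", {
  skip_if_not_installed("sva")
  co <- generate_cohort(cohort_config(n_genes = 200, n_de = 10,
                                      n_control = 20, n_case = 20,
                                      n_batches = 3, batch_shift_sd = 0.8,
                                      seed = 10))
  res <- combat_adjust(co$expr, co$labels)
  ref <- suppressMessages(sva::ComBat(
    co$expr, batch = factor(co$labels$batch),
    mod = stats::model.matrix(~ class, data = co$labels)))
  expect_lt(max(abs(res$adjusted - ref)), 1e-4)
  # the batch model carries finite EB estimates
  expect_true(all(is.finite(res$model$gamma_star)))
  expect_true(all(res$model$delta_star > 0))
})

test_that("degenerate batch inputs are rejected or passed through", {
  co <- generate_cohort(cohort_config(n_genes = 30, n_de = 0,
                                      n_control = 6, n_case = 6,
                                      n_batches = 2, seed = 2))
  lab <- co$labels
  lab$batch[lab$batch == "B2"] <- "B1"
  lab$batch[1] <- "B2"                                 # batch of size 1
  expect_error(combat_adjust(co$expr, lab), "at least 2 samples")

  m <- co$expr
  m[3, ] <- 5                                          # zero-variance gene
  expect_warning(res <- combat_adjust(m, co$labels), "zero-variance")
  expect_equal(unname(res$adjusted[3, ]), rep(5, ncol(m)))
})

test_that("whole batches are assigned to one split", {
  co <- generate_cohort(cohort_config(n_genes = 20, n_de = 0,
                                      n_control = 20, n_case = 20,
                                      n_batches = 4, seed = 1))
  lab <- assign_split(co$labels, "B1")
  expect_true(all(lab$split[lab$batch == "B1"] == "train"))
  expect_true(all(lab$split[lab$batch != "B1"] == "test"))
  # counting oracle: per-split class counts equal the brute-force tally
  for (s in c("train", "test")) for (k in c("control", "case"))
    expect_equal(sum(lab$split == s & lab$class == k),
                 sum(co$labels$batch %in% "B1" == (s == "train") &
                       co$labels$class == k))
  expect_error(assign_split(co$labels, character(0)), "non-empty")
  expect_error(assign_split(co$labels, "B9"), "unknown batch")
  expect_error(assign_split(co$labels, paste0("B", 1:4)), "empty testing")
})
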