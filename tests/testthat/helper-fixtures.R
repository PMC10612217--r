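# Small in-code fixtures shared across test files.

# labels data.frame for a matrix whose first n1 columns are controls
make_labels <- function(m, n_control, batch = "B1") {
  n <- ncol(m)
  data.frame(sample_id = colnames(m),
             class = factor(rep(c("control", "case"), c(n_control, n - n_control)),
                            levels = c("control", "case")),
             batch = rep(batch, length.out = n),
             split = NA_character_, stringsAsFactors = FALSE)
}

# two-class matrix with one dominant separating gene and noise genes
separable_fixture <- function(n_genes = 10, n_per_class = 15, shift = 6,
                              sd = 0.5, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n_per_class, 7, 1), n_genes)
  rownames(m) <- sprintf("g%02d", seq_len(n_genes))
  colnames(m) <- sprintf("s%02d", seq_len(2 * n_per_class))
  case_cols <- n_per_class + seq_len(n_per_class)
  m[1, ] <- rnorm(2 * n_per_class, 7, sd)
  m[1, case_cols] <- m[1, case_cols] + shift
  list(expr = m, labels = make_labels(m, n_per_class), dominant = "g01")
}

# brute-force Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, n * p[o[i]] / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# brute-force pair-counting AUC oracle
auc_oracle <- function(case, control) {
  s <- 0
  for (a in case) for (b in control)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(case) * length(control))
}
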