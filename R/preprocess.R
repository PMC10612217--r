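#' Collapse duplicated gene identifiers by averaging
#'
#' Multiple rows sharing a gene identifier (multiple probes or
#' transcripts per gene) are replaced by their per-sample arithmetic
#' mean.  Row order of the result follows first occurrence in the input,
#' so the operation is idempotent.
#'
#' @param matrix numeric genes x samples matrix; rownames are gene ids,
#'   possibly duplicated.
#' @return matrix with unique rownames.
#' @export
collapse_duplicates <- function(matrix) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0L || ncol(matrix) == 0L)
    stop("empty expression matrix")
  ids <- rownames(matrix)
  if (is.null(ids)) stop("expression matrix must have gene ids as rownames")
  if (!anyDuplicated(ids)) return(matrix)
  f <- factor(ids, levels = unique(ids))
  out <- rowsum(matrix, f, reorder = FALSE) / as.vector(table(f))
  rownames(out) <- levels(f)
  out
}

.validate_labels <- function(matrix, labels) {
  need <- c("sample_id", "class", "batch")
  if (!all(need %in% names(labels)))
    stop("labels must have columns sample_id, class, batch")
  if (anyDuplicated(labels$sample_id))
    stop("duplicate sample ids in labels")
  if (!setequal(labels$sample_id, colnames(matrix)) ||
      nrow(labels) != ncol(matrix))
    stop("labels do not match the matrix columns")
  labels[match(colnames(matrix), labels$sample_id), , drop = FALSE]
}

#' Parametric empirical-Bayes batch adjustment
#'
#' Adjusts additive and multiplicative batch effects in a log-scale
#' expression matrix with the standard parametric location/scale
#' empirical-Bayes procedure: gene-wise standardisation against a
#' covariate-adjusted grand mean and pooled variance, method-of-moments
#' estimation of a normal prior on the additive batch effects (gamma)
#' and an inverse-gamma prior on the multiplicative effects (delta^2),
#' iterative conditional-mean shrinkage of both, then
#' back-transformation.  With `protect_class = TRUE` (default) the
#' class label enters the standardisation design so the case/control
#' contrast is not absorbed into the batch model.
#'
#' Genes with zero pooled variance are passed through unadjusted with a
#' warning, keeping gene sets aligned across stages.  A single-batch
#' matrix is returned unchanged (there is nothing to adjust).
#'
#' @param matrix genes x samples numeric matrix, log2 scale, unique
#'   rownames.
#' @param labels sample annotation (`sample_id`, `class`, `batch`).
#' @param parametric must be `TRUE`; only the parametric priors are
#'   implemented.
#' @param protect_class include the class covariate in the design.
#' @param conv convergence tolerance of the iterative shrinkage solver.
#' @return list with `adjusted` (same shape and dimnames as input) and
#'   `model`, a `batch_model` holding the per-gene grand means and
#'   pooled variances, per-(batch, gene) raw (`gamma_hat`, `delta_hat`)
#'   and shrunken (`gamma_star`, `delta_star`) effect estimates, and the
#'   estimated prior hyperparameters.
#' @export
combat_adjust <- function(matrix, labels, parametric = TRUE,
                          protect_class = TRUE, conv = 1e-4) {
  if (!isTRUE(parametric))
    stop("only the parametric adjustment is implemented")
  labels <- .validate_labels(matrix, labels)
  batch <- factor(labels$batch)
  n_batches <- nlevels(batch)
  tab <- table(batch)
  if (any(tab < 2L))
    stop("each batch needs at least 2 samples (offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "), ")")
  if (n_batches == 1L) {
    model <- structure(list(n_batches = 1L), class = "batch_model")
    return(list(adjusted = matrix, model = model))
  }

  n <- ncol(matrix)
  dat <- matrix
  batch_design <- stats::model.matrix(~ 0 + batch)
  design <- batch_design
  if (protect_class) {
    cls <- factor(labels$class, levels = c("control", "case"))
    design <- cbind(batch_design, case = as.numeric(cls == "case"))
  }

  ## gene-wise least squares: B_hat is (coefs x genes)
  B_hat <- solve(crossprod(design), crossprod(design, t(dat)))
  grand_mean <- crossprod(tab / n, B_hat[seq_len(n_batches), , drop = FALSE])
  resid <- dat - t(design %*% B_hat)
  var_pooled <- rowSums(resid^2) / n

  zero_var <- var_pooled <= .Machine$double.eps
  if (any(zero_var))
    warning(sum(zero_var), " zero-variance gene(s) passed through unadjusted")

  stand_mean <- crossprod(grand_mean, t(rep(1, n)))      # genes x samples
  if (protect_class && ncol(design) > n_batches) {
    extra <- design[, -seq_len(n_batches), drop = FALSE]
    stand_mean <- stand_mean +
      t(extra %*% B_hat[-seq_len(n_batches), , drop = FALSE])
  }
  keep <- which(!zero_var)
  s_data <- (dat[keep, , drop = FALSE] - stand_mean[keep, , drop = FALSE]) /
    sqrt(var_pooled[keep])

  ## per-batch location/scale estimates on standardised data
  idx_by_batch <- split(seq_len(n), batch)
  gamma_hat <- t(vapply(idx_by_batch, function(i)
    rowMeans(s_data[, i, drop = FALSE]), numeric(nrow(s_data))))
  delta_hat <- t(vapply(idx_by_batch, function(i)
    apply(s_data[, i, drop = FALSE], 1, var), numeric(nrow(s_data))))

  ## method-of-moments priors: gamma ~ N(gamma_bar, t2),
  ## delta^2 ~ InvGamma(a, b)
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, var)
  a_prior <- apply(delta_hat, 1, function(d) {
    m <- mean(d); s2 <- var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta_hat, 1, function(d) {
    m <- mean(d); s2 <- var(d); (m * s2 + m^3) / s2
  })

  it_solve <- function(sdat, g_hat, d_hat, g_bar, t2, a, b, n_b) {
    g_old <- g_hat; d_old <- d_hat
    change <- 1
    while (change > conv) {
      g_new <- (t2 * n_b * g_hat + d_old * g_bar) / (t2 * n_b + d_old)
      sum2 <- rowSums((sdat - matrix(g_new, nrow(sdat), ncol(sdat)))^2)
      d_new <- (0.5 * sum2 + b) / (n_b / 2 + a - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old), na.rm = TRUE)
      g_old <- g_new; d_old <- d_new
    }
    list(gamma = g_new, delta = d_new)
  }

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  bayes <- s_data
  for (b in seq_len(n_batches)) {
    i <- idx_by_batch[[b]]
    sol <- it_solve(s_data[, i, drop = FALSE], gamma_hat[b, ], delta_hat[b, ],
                    gamma_bar[b], t2[b], a_prior[b], b_prior[b], length(i))
    gamma_star[b, ] <- sol$gamma
    delta_star[b, ] <- sol$delta
    bayes[, i] <- (s_data[, i, drop = FALSE] - sol$gamma) / sqrt(sol$delta)
  }

  adjusted <- dat
  adjusted[keep, ] <- bayes * sqrt(var_pooled[keep]) +
    stand_mean[keep, , drop = FALSE]

  model <- structure(list(
    n_batches = n_batches, batches = levels(batch),
    grand_mean = as.numeric(grand_mean), var_pooled = var_pooled,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    gamma_prior = list(gamma_bar = gamma_bar, t2 = t2),
    delta_prior = list(a = a_prior, b = b_prior),
    protect_class = protect_class, zero_variance_genes = names(zero_var)[zero_var]),
    class = "batch_model")
  list(adjusted = adjusted, model = model)
}

#' @export
print.batch_model <- function(x, ...) {
  cat("Parametric empirical-Bayes batch model,", x$n_batches, "batch(es)\n")
  if (x$n_batches > 1L) {
    cat("  mean |gamma_star| per batch:",
        paste(signif(rowMeans(abs(x$gamma_star)), 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assign whole batches to the training or testing split
#'
#' Mirrors study-wise (not sample-wise) train/test assignment: every
#' sample of a batch shares one split.
#'
#' @param labels sample annotation with a `batch` column.
#' @param train_batches character vector of batch ids forming the
#'   training set; all remaining batches form the testing set.
#' @return `labels` with the `split` column set to `train`/`test`.
#' @export
assign_split <- function(labels, train_batches) {
  if (length(train_batches) == 0L) stop("train_batches must be non-empty")
  all_b <- unique(labels$batch)
  unknown <- setdiff(train_batches, all_b)
  if (length(unknown))
    stop("unknown batch id(s): ", paste(unknown, collapse = ", "))
  if (length(setdiff(all_b, train_batches)) == 0L)
    stop("all batches assigned to training: empty testing set")
  labels$split <- ifelse(labels$batch %in% train_batches, "train", "test")
  labels
}
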