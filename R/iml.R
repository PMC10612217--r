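#' Column-max normalisation of a per-gene weight table
#'
#' The core statistic of the workflow: each model's per-gene weights are
#' mapped to `|w| / max_g |w|` (so every model contributes on a common
#' 0..1 scale regardless of its native units), and the overall weight of
#' a gene is the row sum of the normalised table, in \[0, number of
#' models\].  A model whose weights are all zero contributes zero to
#' every gene (no division by zero) and triggers a warning.
#'
#' Column maxima may be supplied explicitly (e.g. taken from a full
#' cohort when normalising a subset of rows); by default they are the
#' observed per-column maximum absolute weights.
#'
#' @param raw numeric genes x models matrix of raw weights (signed or
#'   non-negative); rownames are gene ids.
#' @param col_max optional per-model maximum absolute weights.
#' @param n_models expected number of model columns.
#' @return object of class `weight_table`: list with `raw`,
#'   `normalized`, `overall` (named vector) and `gene_ids`.
#' @examples
#' raw <- rbind(IL6 = c(30, -22, 20, -2, 320, -8))
#' wt <- normalize_weight_table(raw, col_max = c(60, 88, 80, 8, 640, 16))
#' wt$overall   # 2.25
#' @export
normalize_weight_table <- function(raw, col_max = NULL, n_models = 6L) {
  raw <- as.matrix(raw)
  if (ncol(raw) != n_models)
    stop("expected ", n_models, " model columns, got ", ncol(raw))
  if (any(!is.finite(raw))) stop("weights must be finite")
  if (is.null(col_max)) col_max <- apply(abs(raw), 2, max)
  if (length(col_max) != ncol(raw))
    stop("col_max must have one entry per model column")
  zero_col <- col_max == 0
  if (any(zero_col)) {
    warning("model column(s) with all-zero weights contribute 0: ",
            paste(colnames(raw)[zero_col], collapse = ", "))
    col_max[zero_col] <- 1          # keeps the column at exactly zero
  }
  normalized <- sweep(abs(raw), 2, col_max, "/")
  overall <- rowSums(normalized)
  structure(list(raw = raw, normalized = normalized, overall = overall,
                 gene_ids = rownames(raw), col_max = col_max),
            class = "weight_table")
}

#' Overall (summed normalised) weights of a weight table
#'
#' @param table a `weight_table` from [normalize_weight_table()], or a
#'   genes x models matrix of already-normalised weights.
#' @return named numeric vector of per-gene overall weights.
#' @export
overall_weights <- function(table) {
  if (inherits(table, "weight_table"))
    return(stats::setNames(rowSums(table$normalized), table$gene_ids))
  m <- as.matrix(table)
  stats::setNames(rowSums(m), rownames(m))
}

#' @export
print.weight_table <- function(x, ...) {
  cat("Weight table:", length(x$gene_ids), "genes x", ncol(x$raw), "models\n")
  ord <- order(x$overall, decreasing = TRUE)
  show <- head(ord, 5)
  cat("  top overall weights:\n")
  for (i in show)
    cat(sprintf("    %-12s %.3f\n", x$gene_ids[i], x$overall[i]))
  invisible(x)
}

#' Select candidate genes by overall weight
#'
#' @param scores named overall-weight vector (or a `weight_table`).
#' @param threshold candidates must have overall weight strictly above
#'   this value (default 1).
#' @return data.frame of class `candidate_set` (`gene`, `overall`),
#'   sorted by descending overall weight; the threshold is attached as
#'   an attribute.
#' @export
select_candidates <- function(scores, threshold = 1.0) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (inherits(scores, "weight_table")) scores <- overall_weights(scores)
  keep <- scores > threshold
  out <- data.frame(gene = names(scores)[keep], overall = unname(scores[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$overall), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("candidate_set", class(out))
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate genes (overall weight >", attr(x, "threshold"), "):",
      nrow(x), "\n")
  print.data.frame(head(x, 10), digits = 3)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Fit the integrated machine-learning (IML) gene-weighting model
#'
#' Fits the six base classifiers (or a subset) on a two-class expression
#' matrix restricted to a candidate gene set, extracts each model's
#' per-gene weights, column-max-normalises them into a common 0..1
#' scale, sums them into per-gene overall weights, and nominates
#' candidate genes whose overall weight exceeds `threshold`.
#'
#' @param x genes x samples expression matrix (log2 scale), typically
#'   restricted to the differentially expressed genes of the training
#'   cohort.
#' @param labels class labels: a factor (`control`/`case`) aligned with
#'   the columns, or a sample-annotation data.frame.
#' @param genes optional character vector restricting `x` to a gene
#'   subset before fitting.
#' @param models which base learners to fit.
#' @param threshold overall-weight cutoff for candidate genes.
#' @param seed integer seed; all tuning, resampling and stochastic fits
#'   derive from it, so identical calls give identical fits.
#' @param cv compute 10-fold cross-validated accuracy per model (can be
#'   disabled for speed).
#' @param control an [iml_control()] with the per-model tuning rules.
#' @return an object of class `iml` with components `fits` (per-model
#'   `iml_learner`s), `weights` (a `weight_table`), `candidates` (a
#'   `candidate_set`), `accuracy` (per-model train/cv accuracy),
#'   `levels`, `genes`, `threshold`, `seed` and `call`.
#' @seealso [predict.iml()], [coef.iml()], [plot.iml()], [summary.iml()]
#' @examples
#' co <- generate_cohort(cohort_config(n_genes = 30, n_de = 3,
#'                                     n_control = 20, n_case = 20,
#'                                     logfc_range = c(2, 3), seed = 1))
#' fit <- iml_fit(co$expr, co$labels, models = c("lasso", "dt"),
#'                cv = FALSE, seed = 1)
#' coef(fit)[1:5]
#' @export
iml_fit <- function(x, labels, genes = NULL,
                    models = c("lasso", "svm", "rf", "dt", "gbm", "nn"),
                    threshold = 1.0, seed = 1L, cv = TRUE,
                    control = iml_control()) {
  cl <- match.call()
  models <- match.arg(models, several.ok = TRUE)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(x))
    if (length(missing))
      stop("genes not in the matrix: ", paste(head(missing, 5), collapse = ", "))
    x <- x[genes, , drop = FALSE]
  }
  if (is.data.frame(labels)) labels <- .validate_labels(x, labels)

  fits <- vector("list", length(models))
  names(fits) <- models
  for (m in models)
    fits[[m]] <- tune_and_fit(m, x, labels, seed = seed, control = control)

  raw <- vapply(fits, function(f) f$raw_weights[rownames(x)],
                numeric(nrow(x)))
  if (nrow(x) == 1L) raw <- matrix(raw, 1L, dimnames = list(rownames(x), models))
  wt <- normalize_weight_table(raw, n_models = length(models))
  cand <- select_candidates(wt, threshold)

  acc <- data.frame(model = models,
                    train = vapply(fits, `[[`, numeric(1), "train_accuracy"),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (cv) {
    acc$cv <- vapply(models, function(m)
      cv_accuracy(fits[[m]], x, labels, folds = control$cv_folds, seed = seed),
      numeric(1))
  }

  structure(list(fits = fits, weights = wt, candidates = cand,
                 accuracy = acc, genes = rownames(x),
                 levels = c("control", "case"), threshold = threshold,
                 seed = seed, control = control, call = cl),
            class = "iml")
}

#' @export
print.iml <- function(x, ...) {
  cat("Integrated machine-learning gene-weighting model\n")
  cat("  models:", paste(x$accuracy$model, collapse = ", "), "\n")
  cat("  genes:", length(x$genes), " candidates (overall >",
      x$threshold, "):", nrow(x$candidates), "\n")
  if (nrow(x$candidates))
    cat("  top:", paste(head(x$candidates$gene, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.iml <- function(object, ...) {
  structure(list(accuracy = object$accuracy,
                 candidates = object$candidates,
                 n_genes = length(object$genes),
                 threshold = object$threshold), class = "summary.iml")
}

#' @export
print.summary.iml <- function(x, ...) {
  cat("IML model over", x$n_genes, "genes\n\nPer-model accuracy:\n")
  print(x$accuracy, digits = 3, row.names = FALSE)
  cat("\n")
  print(x$candidates)
  invisible(x)
}

#' Extract gene weights from a fitted IML model
#'
#' @param object an `iml` fit.
#' @param type `"overall"` (default, the summed normalised weights),
#'   `"normalized"` (genes x models matrix) or `"raw"`.
#' @param ... unused.
#' @return named vector or matrix of weights.
#' @export
coef.iml <- function(object, type = c("overall", "normalized", "raw"), ...) {
  type <- match.arg(type)
  switch(type,
         overall = stats::setNames(object$weights$overall,
                                   object$weights$gene_ids),
         normalized = object$weights$normalized,
         raw = object$weights$raw)
}

#' Predict class membership from a fitted IML model
#'
#' Per-model case probabilities are averaged (unweighted soft vote)
#' unless a single model is requested.
#'
#' @param object an `iml` fit.
#' @param newdata genes x samples matrix covering the fitted gene set.
#' @param type `"class"`, `"prob"` or `"votes"` (per-model probability
#'   matrix).
#' @param models subset of fitted models to use.
#' @param ... unused.
#' @return factor of classes, probability vector, or matrix.
#' @export
predict.iml <- function(object, newdata, type = c("class", "prob", "votes"),
                        models = names(object$fits), ...) {
  type <- match.arg(type)
  models <- intersect(models, names(object$fits))
  if (!length(models)) stop("no fitted model selected")
  missing <- setdiff(object$genes, rownames(newdata))
  if (length(missing))
    stop("newdata lacks fitted genes: ", paste(head(missing, 5), collapse = ", "))
  X <- t(newdata[object$genes, , drop = FALSE])
  votes <- vapply(models, function(m) {
    f <- object$fits[[m]]
    as.numeric(f$predict_prob(f$object, X))
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) votes <- matrix(votes, 1L, dimnames = list(NULL, models))
  rownames(votes) <- rownames(X)
  if (type == "votes") return(votes)
  prob <- rowMeans(votes)
  if (type == "prob") return(prob)
  factor(ifelse(prob > 0.5, "case", "control"), levels = object$levels)
}

#' Lollipop plot of overall gene weights
#'
#' Genes ordered by overall weight with the candidate threshold marked.
#'
#' @param x an `iml` fit or a `weight_table`.
#' @param top show at most this many genes.
#' @param threshold candidate cutoff line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.iml <- function(x, top = 30L, threshold = x$threshold, ...) {
  ow <- sort(coef(x, "overall"), decreasing = TRUE)
  ow <- head(ow, top)
  n <- length(ow)
  op <- par(mar = c(4, 7, 2, 1)); on.exit(par(op))
  plot(ow, seq_len(n), xlim = c(0, max(ow) * 1.05), ylim = c(n + 0.5, 0.5),
       xlab = "overall weight", ylab = "", yaxt = "n", pch = 19,
       main = "Overall IML gene weights", ...)
  segments(0, seq_len(n), ow, seq_len(n), col = "grey60")
  points(ow, seq_len(n), pch = 19,
         col = ifelse(ow > threshold, "firebrick", "grey40"))
  axis(2, at = seq_len(n), labels = names(ow), las = 2, cex.axis = 0.7)
  abline(v = threshold, lty = 2)
  invisible(x)
}
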