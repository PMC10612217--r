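#' Configuration for an end-to-end analysis run
#'
#' Collects every stage parameter with defaults equal to the workflow's
#' standard settings: duplicate collapsing, parametric batch
#' adjustment, DEG thresholds |logFC| > 0.7 and FDR < 0.05 on the
#' training split, six-model IML with candidate threshold 1, rank-sum
#' re-filtering at alpha 0.05 plus per-gene AUC on the testing split,
#' and NNLS deconvolution with Spearman correlation for the immune
#' stage.
#'
#' Either supply a synthetic [cohort_config()] (`cohort`) or paths to
#' expression/label TSVs (`expr_path`, `labels_path`).
#'
#' @param cohort a [cohort_config()] for synthetic input (default: a
#'   2-batch cohort with planted DE genes).
#' @param expr_path,labels_path TSV inputs used instead of synthetic
#'   generation when both are given.
#' @param train_batches batches assigned to the training split (default:
#'   all but the last batch).
#' @param lfc_threshold,fdr_threshold DEG thresholds.
#' @param models,weight_threshold,cv,control IML stage settings (see
#'   [iml_fit()]).
#' @param test_alpha rank-sum re-filter level on the testing split.
#' @param immune run the immune-correlation stage (synthetic signature +
#'   mixtures aligned with the cohort samples).
#' @param signature optional `signature_matrix` for the immune stage.
#' @param seed master seed; stage seeds derive from it.
#' @param out_dir optional directory; when set, stage artifacts are
#'   written there as TSV.
#' @return list of class `iml_config`.
#' @export
iml_config <- function(cohort = cohort_config(n_genes = 2000, n_de = 40,
                                              n_control = 90, n_case = 90,
                                              logfc_range = c(1.2, 2.5),
                                              noise_sd = 1, n_batches = 2,
                                              batch_shift_sd = 0.5,
                                              batch_props = c(2, 1) / 3,
                                              dup_rate = 0.05, seed = 1),
                       expr_path = NULL, labels_path = NULL,
                       train_batches = NULL,
                       lfc_threshold = 0.7, fdr_threshold = 0.05,
                       models = c("lasso", "svm", "rf", "dt", "gbm", "nn"),
                       weight_threshold = 1.0, cv = FALSE,
                       control = iml_control(),
                       test_alpha = 0.05, immune = TRUE, signature = NULL,
                       seed = 1L, out_dir = NULL) {
  structure(list(cohort = cohort, expr_path = expr_path,
                 labels_path = labels_path, train_batches = train_batches,
                 lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold,
                 models = models, weight_threshold = weight_threshold,
                 cv = cv, control = control, test_alpha = test_alpha,
                 immune = immune, signature = signature,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "iml_config")
}

#' Run the full diagnostic-gene discovery pipeline
#'
#' Executes the stages in order — input (synthetic generation or TSV
#' loading), preprocessing (duplicate collapsing, batch adjustment,
#' batch-wise train/test split), differential expression on the
#' training split, IML weighting and candidate selection, testing-set
#' validation (rank-sum re-filter and per-gene AUC) and, optionally,
#' immune deconvolution with gene-fraction correlation — and returns a
#' structured, reproducible run report.  A failing stage aborts with
#' the stage named.
#'
#' @param config an [iml_config()].
#' @param verbose print stage progress.
#' @return object of class `iml_run`: list with `config`, `data`
#'   (adjusted matrix + labels), `deg` (full table, counts, selected
#'   genes), `fit` (the `iml` object), `accuracy`, `candidates`,
#'   `validation` (retained candidates, per-gene train/test AUC),
#'   `immune` (fraction estimates + correlation table or `NULL`), and
#'   `seed`.
#' @examples
#' \donttest{
#' cfg <- iml_config(cohort = cohort_config(n_genes = 300, n_de = 10,
#'                                          n_control = 40, n_case = 40,
#'                                          logfc_range = c(1.5, 2.5),
#'                                          n_batches = 2, seed = 1),
#'                   models = c("lasso", "rf", "dt"), immune = FALSE)
#' rep <- run_pipeline(cfg, verbose = FALSE)
#' rep$deg$n_selected
#' }
#' @export
run_pipeline <- function(config = iml_config(), verbose = TRUE) {
  stage <- function(name, expr) {
    if (verbose) message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  save_tsv <- function(obj, file, writer = write.table) {
    if (!is.null(out_dir)) {
      if (identical(writer, write.table))
        write.table(obj, file.path(out_dir, file), sep = "\t", quote = FALSE,
                    row.names = FALSE)
      else writer(obj, file.path(out_dir, file))
    }
  }

  ## --- input -------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$expr_path) && !is.null(config$labels_path)) {
    expr <- stage("load", read_expression(config$expr_path))
    labels <- stage("load", read_labels(config$labels_path))
    labels <- .validate_labels(expr, labels)
  } else {
    co <- stage("simulate", generate_cohort(config$cohort))
    expr <- co$expr; labels <- co$labels; truth <- co$truth
    save_tsv(expr, "expr_raw.tsv", write_expression)
    save_tsv(labels, "labels.tsv")
  }

  ## --- preprocessing -----------------------------------------------------
  expr <- stage("collapse", collapse_duplicates(expr))
  n_batches <- length(unique(labels$batch))
  adj <- if (n_batches > 1L) {
    stage("combat", combat_adjust(expr, labels))
  } else list(adjusted = expr, model = NULL)
  expr_adj <- adj$adjusted
  train_b <- config$train_batches
  if (is.null(train_b)) {
    all_b <- unique(labels$batch)
    train_b <- if (length(all_b) > 1L) all_b[-length(all_b)] else all_b[1]
  }
  labels <- if (n_batches > 1L) {
    stage("split", assign_split(labels, train_b))
  } else transform(labels, split = "train")
  save_tsv(expr_adj, "expr_adjusted.tsv", write_expression)

  is_train <- labels$split == "train"
  has_test <- any(!is_train)
  expr_train <- expr_adj[, labels$sample_id[is_train], drop = FALSE]
  labels_train <- labels[is_train, , drop = FALSE]

  ## --- differential expression (training split) --------------------------
  deg_tab <- stage("deg", run_dge(expr_train, labels_train,
                                  config$lfc_threshold, config$fdr_threshold))
  deg_genes <- deg_tab$gene[deg_tab$selected]
  if (length(deg_genes) < 2L)
    stop("pipeline stage 'deg' failed: fewer than 2 DEGs selected",
         call. = FALSE)
  save_tsv(deg_tab, "deg.tsv")

  ## --- IML ensemble -------------------------------------------------------
  fit <- stage("iml", iml_fit(expr_train, labels_train, genes = deg_genes,
                              models = config$models,
                              threshold = config$weight_threshold,
                              seed = config$seed, cv = config$cv,
                              control = config$control))
  acc <- fit$accuracy
  if (has_test) {
    expr_test <- expr_adj[, labels$sample_id[!is_train], drop = FALSE]
    labels_test <- labels[!is_train, , drop = FALSE]
    acc$test <- vapply(acc$model, function(m)
      evaluate_accuracy(fit$fits[[m]], expr_test[fit$genes, , drop = FALSE],
                        labels_test), numeric(1))
  }
  save_tsv(data.frame(gene = fit$weights$gene_ids, fit$weights$normalized,
                      overall = fit$weights$overall, check.names = FALSE),
           "weights.tsv")
  save_tsv(acc, "accuracy.tsv")

  ## --- testing-set validation --------------------------------------------
  validation <- NULL
  if (has_test && nrow(fit$candidates) > 0L) {
    retained <- stage("validate",
                      test_set_filter(fit$candidates, expr_test, labels_test,
                                      alpha = config$test_alpha))
    auc_tab <- data.frame(
      gene = retained$gene,
      auc_train = vapply(retained$gene, function(g)
        auc_mann_whitney(expr_train[g, ], labels_train, orient = TRUE),
        numeric(1)),
      auc_test = vapply(retained$gene, function(g)
        auc_mann_whitney(expr_test[g, ], labels_test, orient = TRUE),
        numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
    validation <- list(retained = retained,
                       excluded = attr(retained, "excluded"),
                       auc = auc_tab)
    save_tsv(auc_tab, "auc.tsv")
  }

  ## --- immune correlation -------------------------------------------------
  immune <- NULL
  if (isTRUE(config$immune) && nrow(fit$candidates) > 0L) {
    immune <- stage("immune", {
      sig <- config$signature
      if (is.null(sig)) sig <- synthetic_signature(seed = config$seed)
      mix <- generate_mixture(sig, n_samples = ncol(expr_adj), noise_sd = 0.5,
                              seed = config$seed + 1L)
      colnames(mix$expr) <- colnames(expr_adj)
      fr <- deconvolve_fractions(mix$expr, sig)
      corr <- correlate_gene_fractions(expr_adj, fr,
                                       genes = fit$candidates$gene)
      save_tsv(corr, "immune_correlation.tsv")
      list(fractions = fr, correlation = corr,
           truth_fractions = mix$truth$mixing_fractions)
    })
  }

  structure(list(config = config,
                 data = list(expr = expr_adj, labels = labels, truth = truth,
                             batch_model = adj$model),
                 deg = list(table = deg_tab, genes = deg_genes,
                            n_selected = length(deg_genes),
                            n_up = sum(deg_tab$direction == "up"),
                            n_down = sum(deg_tab$direction == "down")),
                 fit = fit, accuracy = acc, candidates = fit$candidates,
                 validation = validation, immune = immune,
                 seed = config$seed),
            class = "iml_run")
}

#' @export
print.iml_run <- function(x, ...) {
  cat("IML pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("  samples: ", nrow(x$data$labels), " (",
      sum(x$data$labels$split == "train"), " train / ",
      sum(x$data$labels$split == "test"), " test)\n", sep = "")
  cat("  DEGs: ", x$deg$n_selected, " (", x$deg$n_up, " up / ",
      x$deg$n_down, " down)\n", sep = "")
  cat("  candidates (overall > ", x$fit$threshold, "): ",
      nrow(x$candidates), "\n", sep = "")
  if (!is.null(x$validation))
    cat("  retained after testing-set filter: ",
        nrow(x$validation$retained), "\n", sep = "")
  acc <- x$accuracy
  cat("  accuracy: ",
      paste(sprintf("%s=%.2f", acc$model, acc$train), collapse = " "),
      " (train)\n", sep = "")
  invisible(x)
}
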