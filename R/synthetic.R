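#' Configuration for a synthetic two-class expression cohort
#'
#' Describes a log2-scale microarray-like cohort with two classes
#' (`control` and `case`), optional additive batch structure, a set of
#' planted differentially expressed genes with known signed log2 fold
#' changes, and optional duplicated gene identifiers.  The generator is a
#' pure function of this configuration, including its seed.
#'
#' Baseline per-gene means are drawn from a normal distribution on the
#' log2 scale (`base_mean` 7, `base_sd` 2), resembling summarised
#' microarray intensities.  Planted genes add a signed class-mean shift to
#' the case samples; batch effects are additive per-(batch, gene) normal
#' offsets; residual noise is i.i.d. normal per observation.
#'
#' @param n_genes number of distinct genes.
#' @param n_control,n_case samples per class.
#' @param n_de number of planted differentially expressed genes.
#' @param logfc_range length-2 positive range for the absolute planted
#'   log2 fold change (case minus control).
#' @param frac_up share of planted genes upregulated in cases.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param n_batches number of batches (studies).
#' @param batch_shift_sd standard deviation of the additive per-(batch,
#'   gene) offsets; 0 disables batch effects.
#' @param batch_scale_sd standard deviation (on the log scale) of
#'   multiplicative per-(batch, gene) noise-scale factors; 0 (the
#'   default) keeps batch effects purely additive.
#' @param batch_props optional per-batch sample proportions (defaults to
#'   equal); applied within each class so batches stay class-balanced.
#' @param dup_rate fraction of genes emitted a second time under the same
#'   identifier (independent noise around the same signal), exercising
#'   duplicate collapsing.
#' @param base_mean,base_sd distribution of baseline per-gene means.
#' @param seed integer seed; identical configurations give identical
#'   cohorts.
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_genes = 2000L, n_control = 60L, n_case = 60L,
                          n_de = 40L, logfc_range = c(0.7, 2.5),
                          frac_up = 0.7, noise_sd = 1,
                          n_batches = 1L, batch_shift_sd = 0,
                          batch_scale_sd = 0, batch_props = NULL,
                          dup_rate = 0, base_mean = 7, base_sd = 2,
                          seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_control = as.integer(n_control),
              n_case = as.integer(n_case), n_de = as.integer(n_de),
              logfc_range = as.numeric(logfc_range), frac_up = frac_up,
              noise_sd = noise_sd, n_batches = as.integer(n_batches),
              batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
              batch_props = batch_props, dup_rate = dup_rate,
              base_mean = base_mean, base_sd = base_sd, seed = as.integer(seed))
  .check_scalar <- function(x, field, min = -Inf, max = Inf) {
    if (length(x) != 1L || !is.finite(x) || x < min || x > max)
      stop("invalid cohort configuration: field '", field, "'", call. = FALSE)
  }
  .check_scalar(cfg$n_genes, "n_genes", min = 1)
  .check_scalar(cfg$n_control, "n_control", min = 1)
  .check_scalar(cfg$n_case, "n_case", min = 1)
  .check_scalar(cfg$n_de, "n_de", min = 0, max = cfg$n_genes)
  if (length(cfg$logfc_range) != 2L || any(!is.finite(cfg$logfc_range)) ||
      cfg$logfc_range[1] <= 0 || diff(cfg$logfc_range) < 0)
    stop("invalid cohort configuration: field 'logfc_range'", call. = FALSE)
  .check_scalar(cfg$frac_up, "frac_up", min = 0, max = 1)
  .check_scalar(cfg$noise_sd, "noise_sd", min = 0)
  if (cfg$noise_sd <= 0)
    stop("invalid cohort configuration: field 'noise_sd'", call. = FALSE)
  .check_scalar(cfg$n_batches, "n_batches", min = 1)
  .check_scalar(cfg$batch_shift_sd, "batch_shift_sd", min = 0)
  .check_scalar(cfg$batch_scale_sd, "batch_scale_sd", min = 0)
  .check_scalar(cfg$dup_rate, "dup_rate", min = 0, max = 1)
  .check_scalar(cfg$seed, "seed")
  if (!is.null(cfg$batch_props)) {
    if (length(cfg$batch_props) != cfg$n_batches || any(cfg$batch_props <= 0))
      stop("invalid cohort configuration: field 'batch_props'", call. = FALSE)
    cfg$batch_props <- cfg$batch_props / sum(cfg$batch_props)
  }
  class(cfg) <- "cohort_config"
  cfg
}

## deterministic allocation of n items over batch proportions
.alloc_batches <- function(n, props) {
  k <- length(props)
  counts <- floor(n * props)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(n * props - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  rep(seq_len(k), counts)
}

#' Generate a synthetic two-class expression cohort with known truth
#'
#' Emits a genes-by-samples log2 expression matrix, a sample-annotation
#' table and a ground-truth record (planted log2 fold changes and batch
#' offsets).  Exactly `n_de` genes carry a planted class-mean difference;
#' duplicated identifiers, when requested, are appended as extra rows
#' with independent noise around the same underlying signal.
#'
#' @param cfg a [cohort_config()].
#' @return a list of class `iml_cohort` with components
#'   \describe{
#'     \item{expr}{numeric matrix, genes (rownames, possibly duplicated)
#'       by samples (unique colnames), log2 scale.}
#'     \item{labels}{data.frame with `sample_id`, `class` (factor
#'       control/case), `batch`, `split` (`NA` until assigned).}
#'     \item{truth}{list with `de_genes` (data.frame `gene_id`, `logfc`),
#'       `batch_offsets` (batches x genes matrix) and the `config`.}
#'   }
#' @examples
#' co <- generate_cohort(cohort_config(n_genes = 100, n_de = 5, seed = 1))
#' dim(co$expr)
#' head(co$truth$de_genes)
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) cfg <- do.call(cohort_config, cfg)
  set.seed(cfg$seed)
  g_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  mu <- rnorm(cfg$n_genes, cfg$base_mean, cfg$base_sd)

  beta <- numeric(cfg$n_genes)
  de_idx <- integer(0)
  if (cfg$n_de > 0) {
    de_idx <- sort(sample.int(cfg$n_genes, cfg$n_de))
    mag <- runif(cfg$n_de, cfg$logfc_range[1], cfg$logfc_range[2])
    sign_up <- rbinom(cfg$n_de, 1L, cfg$frac_up) * 2L - 1L
    beta[de_idx] <- mag * sign_up
  }

  n <- cfg$n_control + cfg$n_case
  s_ids <- sprintf("S%04d", seq_len(n))
  cls <- factor(rep(c("control", "case"), c(cfg$n_control, cfg$n_case)),
                levels = c("control", "case"))
  props <- if (is.null(cfg$batch_props)) rep(1 / cfg$n_batches, cfg$n_batches)
           else cfg$batch_props
  batch <- integer(n)
  batch[cls == "control"] <- .alloc_batches(cfg$n_control, props)
  batch[cls == "case"] <- .alloc_batches(cfg$n_case, props)
  batch_id <- sprintf("B%d", batch)

  gamma <- matrix(0, cfg$n_batches, cfg$n_genes,
                  dimnames = list(sprintf("B%d", seq_len(cfg$n_batches)), g_ids))
  if (cfg$batch_shift_sd > 0)
    gamma[] <- rnorm(length(gamma), 0, cfg$batch_shift_sd)
  delta <- matrix(1, cfg$n_batches, cfg$n_genes)
  if (cfg$batch_scale_sd > 0)
    delta[] <- exp(rnorm(length(delta), 0, cfg$batch_scale_sd))

  signal <- mu + outer(beta, as.numeric(cls == "case"))      # genes x samples
  signal <- signal + t(gamma[batch, , drop = FALSE])
  scale_fac <- t(sqrt(delta[batch, , drop = FALSE]))
  expr <- signal + scale_fac * matrix(rnorm(cfg$n_genes * n, 0, cfg$noise_sd),
                                      cfg$n_genes, n)

  n_dup <- round(cfg$dup_rate * cfg$n_genes)
  if (n_dup > 0) {
    dup_idx <- sort(sample.int(cfg$n_genes, n_dup))
    dup <- signal[dup_idx, , drop = FALSE] +
      scale_fac[dup_idx, , drop = FALSE] *
        matrix(rnorm(n_dup * n, 0, cfg$noise_sd), n_dup, n)
    rownames(dup) <- g_ids[dup_idx]
    rownames(expr) <- g_ids
    expr <- rbind(expr, dup)
  } else {
    rownames(expr) <- g_ids
  }
  colnames(expr) <- s_ids

  labels <- data.frame(sample_id = s_ids, class = cls, batch = batch_id,
                       split = NA_character_, stringsAsFactors = FALSE)
  truth <- list(
    de_genes = data.frame(gene_id = g_ids[de_idx], logfc = beta[de_idx],
                          stringsAsFactors = FALSE),
    batch_offsets = gamma,
    config = cfg)
  structure(list(expr = expr, labels = labels, truth = truth),
            class = "iml_cohort")
}

#' @export
print.iml_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic expression cohort:", nrow(x$expr), "rows (",
      cfg$n_genes, "genes ) x", ncol(x$expr), "samples\n")
  cat("  classes: ", cfg$n_control, " control / ", cfg$n_case, " case; ",
      cfg$n_batches, " batch(es); ", nrow(x$truth$de_genes),
      " planted DE genes\n", sep = "")
  invisible(x)
}

#' Synthetic immune-cell signature matrix
#'
#' Builds a non-negative reference expression matrix (genes by cell
#' types) on the linear scale.  Each cell type receives a block of
#' marker genes expressed well above the shared baseline, so columns are
#' linearly independent and deconvolution is well posed.  This is a
#' synthetic stand-in for published leukocyte signature matrices, which
#' are external artifacts; it reproduces their structure (marker-driven,
#' non-negative, column-distinct), not their gene content.
#'
#' @param n_genes number of signature genes.
#' @param cell_types character vector of cell-type names (>= 2).
#' @param marker_strength mean expression of a marker gene in its own
#'   cell type, relative to the baseline mean of 1.
#' @param seed integer seed.
#' @return numeric matrix genes x cell types, class `signature_matrix`.
#' @export
synthetic_signature <- function(n_genes = 200L,
                                cell_types = c("monocyte", "neutrophil",
                                               "cd8_t", "cd4_t", "nk",
                                               "b_cell"),
                                marker_strength = 20, seed = 1L) {
  k <- length(cell_types)
  if (k < 2L) stop("need at least 2 cell types")
  if (n_genes < k) stop("need at least one gene per cell type")
  set.seed(seed)
  sig <- matrix(rgamma(n_genes * k, shape = 2, rate = 2), n_genes, k,
                dimnames = list(sprintf("SG%04d", seq_len(n_genes)),
                                cell_types))
  marker_of <- rep(seq_len(k), length.out = n_genes)
  boost <- rgamma(n_genes, shape = 4, rate = 4 / marker_strength)
  sig[cbind(seq_len(n_genes), marker_of)] <-
    sig[cbind(seq_len(n_genes), marker_of)] + boost
  class(sig) <- c("signature_matrix", class(sig))
  sig
}

#' Simulate bulk mixtures from a signature matrix
#'
#' Each sample's expression is `signature %*% fractions + noise`, with
#' cell-type fractions drawn from a flat Dirichlet on the simplex (or
#' supplied directly) and recorded as ground truth.
#'
#' @param signature genes x cell-types non-negative matrix (see
#'   [synthetic_signature()]).
#' @param n_samples number of mixture samples (>= 1).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed.
#' @param fractions optional cell-types x samples matrix of fractions
#'   (columns must sum to 1); overrides the Dirichlet draw.
#' @return list of class `iml_mixture`: `expr` (genes x samples) and
#'   `truth$mixing_fractions` (cell types x samples).
#' @export
generate_mixture <- function(signature, n_samples, noise_sd = 0, seed = 1L,
                             fractions = NULL) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (ncol(signature) < 2L) stop("signature needs >= 2 cell types")
  if (any(colSums(abs(signature)) == 0)) stop("signature has an all-zero column")
  set.seed(seed)
  k <- ncol(signature)
  if (is.null(fractions)) {
    fractions <- matrix(rgamma(k * n_samples, shape = 1), k, n_samples)
    fractions <- sweep(fractions, 2, colSums(fractions), "/")
  } else {
    fractions <- as.matrix(fractions)
    if (nrow(fractions) != k || ncol(fractions) != n_samples)
      stop("fractions must be cell-types x samples")
    if (any(fractions < 0) || any(abs(colSums(fractions) - 1) > 1e-8))
      stop("fractions must be non-negative and sum to 1 per sample")
  }
  rownames(fractions) <- colnames(signature)
  expr <- unclass(signature) %*% fractions
  if (noise_sd > 0)
    expr <- expr + matrix(rnorm(length(expr), 0, noise_sd), nrow(expr))
  colnames(expr) <- sprintf("M%04d", seq_len(n_samples))
  colnames(fractions) <- colnames(expr)
  structure(list(expr = expr,
                 truth = list(mixing_fractions = fractions,
                              signature = signature)),
            class = "iml_mixture")
}
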