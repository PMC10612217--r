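#' Per-gene log2 fold change
#'
#' Case-class mean minus control-class mean per gene, on the log2 scale
#' of the input matrix.
#'
#' @param matrix genes x samples numeric matrix.
#' @param labels sample annotation with `class` in control/case.
#' @return named numeric vector of log2 fold changes.
#' @export
log_fold_change <- function(matrix, labels) {
  labels <- .validate_labels(matrix, labels)
  is_case <- labels$class == "case"
  if (!any(is_case) || all(is_case)) stop("both classes must be present")
  rowMeans(matrix[, is_case, drop = FALSE]) -
    rowMeans(matrix[, !is_case, drop = FALSE])
}

## Newton inversion of the trigamma function, used by the
## method-of-moments fit of the scaled inverse-chi-square prior.
.trigamma_inverse <- function(y, tol = 1e-8, maxit = 50L) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(maxit)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) / x < tol) break
  }
  x
}

#' Moderated two-sample t-statistics with empirical-Bayes variance
#' shrinkage
#'
#' Per-gene two-sample t-statistics whose variance estimates are shrunk
#' toward a common prior: the per-gene residual variances `s^2` (pooled,
#' `d = n1 + n2 - 2` df) are modelled as scaled inverse chi-square with
#' prior df `d0` and prior variance `s0^2`, estimated by method of
#' moments on the log variances (closed form via trigamma inversion).
#' The posterior variance is `s2_post = (d0 s0^2 + d s^2) / (d0 + d)`;
#' the moderated statistic is `logFC / sqrt(s2_post (1/n1 + 1/n2))` with
#' `d0 + d` degrees of freedom and a two-sided p-value.
#'
#' When the moment estimate of the prior fails (e.g. the log-variance
#' spread is not estimable), the prior df falls back to `d0 = 0`,
#' reducing every statistic to the ordinary pooled-variance t-test.
#' Forcing `d0 = Inf` uses the prior variance alone with normal-like
#' large df.
#'
#' @param matrix genes x samples numeric matrix (log2 scale).
#' @param labels sample annotation with `class`.
#' @param d0 optional forced prior degrees of freedom (`NULL` =
#'   estimate; `0` = ordinary t; `Inf` = fully shrunk).
#' @return list with `table` (data.frame `gene`, `logFC`, `t`, `p`,
#'   `df`) and `params` (`d0`, `s0_sq`, residual `df`, per-gene `s2`).
#' @export
moderated_t <- function(matrix, labels, d0 = NULL) {
  labels <- .validate_labels(matrix, labels)
  is_case <- labels$class == "case"
  n1 <- sum(!is_case); n2 <- sum(is_case)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per class")
  lfc <- log_fold_change(matrix, labels)

  ctr <- matrix
  ctr[, !is_case] <- matrix[, !is_case] - rowMeans(matrix[, !is_case, drop = FALSE])
  ctr[, is_case] <- matrix[, is_case] - rowMeans(matrix[, is_case, drop = FALSE])
  d <- n1 + n2 - 2L
  s2 <- rowSums(ctr^2) / d
  if (all(s2 <= .Machine$double.eps))
    stop("all genes have zero residual variance")

  if (is.null(d0)) {
    ok <- s2 > .Machine$double.eps
    z <- log(s2[ok])
    e <- z - digamma(d / 2) + log(d / 2)
    e_bar <- mean(e)
    e_var <- var(e) - trigamma(d / 2)
    if (is.finite(e_var) && e_var > 0) {
      half_d0 <- .trigamma_inverse(e_var)
      d0 <- 2 * half_d0
      s0_sq <- exp(e_bar + digamma(half_d0) - log(half_d0))
    } else if (is.finite(e_var)) {
      d0 <- Inf
      s0_sq <- exp(e_bar)
    } else {
      d0 <- 0                       # fallback: ordinary t
      s0_sq <- mean(s2)
    }
  } else {
    s0_sq <- if (is.finite(d0) && d0 > 0) {
      z <- log(s2[s2 > 0]); exp(mean(z))
    } else mean(s2[s2 > 0])
  }

  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else (d0 * s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tt <- lfc / se
  df_total <- if (is.infinite(d0)) 1e6 else d0 + d
  p <- 2 * pt(-abs(tt), df = df_total)

  list(table = data.frame(gene = rownames(matrix), logFC = lfc, t = tt,
                          p = p, df = df_total, row.names = NULL,
                          stringsAsFactors = FALSE),
       params = list(d0 = d0, s0_sq = s0_sq, df_resid = d, s2 = s2))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values controlling the false discovery rate.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Select differentially expressed genes by dual thresholds
#'
#' A gene is selected iff `|logFC| > lfc_threshold` (strict) and
#' `fdr < fdr_threshold` (strict); the direction is `up`/`down` by the
#' sign of logFC for selected genes and `ns` otherwise.
#'
#' @param result data.frame with at least `gene`, `logFC`, `fdr`
#'   columns (see [run_dge()]).
#' @param lfc_threshold positive log2-fold-change cutoff.
#' @param fdr_threshold positive FDR cutoff.
#' @return `result` with added `direction` and logical `selected`.
#' @export
select_degs <- function(result, lfc_threshold = 0.7, fdr_threshold = 0.05) {
  if (lfc_threshold <= 0 || fdr_threshold <= 0)
    stop("thresholds must be positive")
  if (!all(c("gene", "logFC", "fdr") %in% names(result)))
    stop("result must have columns gene, logFC, fdr")
  sel <- abs(result$logFC) > lfc_threshold & result$fdr < fdr_threshold
  result$selected <- sel
  result$direction <- ifelse(!sel, "ns", ifelse(result$logFC > 0, "up", "down"))
  attr(result, "thresholds") <- c(lfc = lfc_threshold, fdr = fdr_threshold)
  result
}

#' Differential expression analysis: moderated t + BH-FDR + thresholds
#'
#' Convenience wrapper running [moderated_t()], [bh_adjust()] and
#' [select_degs()] in sequence on one split of the cohort.
#'
#' @inheritParams moderated_t
#' @inheritParams select_degs
#' @param split restrict to samples of this split (`NULL` = all).
#' @return a DEG table (data.frame) with `gene`, `logFC`, `t`, `p`,
#'   `fdr`, `direction`, `selected`; moderation parameters are attached
#'   as attribute `"params"`.
#' @export
run_dge <- function(matrix, labels, lfc_threshold = 0.7, fdr_threshold = 0.05,
                    split = NULL) {
  if (!is.null(split)) {
    keep <- labels$split %in% split
    if (!any(keep)) stop("no samples in split '", split, "'")
    labels <- labels[keep, , drop = FALSE]
    matrix <- matrix[, labels$sample_id, drop = FALSE]
  }
  mt <- moderated_t(matrix, labels)
  tab <- mt$table
  tab$fdr <- bh_adjust(tab$p)
  tab <- select_degs(tab, lfc_threshold, fdr_threshold)
  attr(tab, "params") <- mt$params
  tab
}
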