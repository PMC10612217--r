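#' Signature-based immune-cell fraction estimation
#'
#' Estimates per-sample cell-type fractions by constrained regression of
#' each bulk mixture column on the signature profiles.  The default
#' solver is non-negative least squares (deterministic, exact for
#' noiseless mixtures of linearly independent signatures); the
#' `"nu-svr"` mode mirrors support-vector-regression-based
#' deconvolution: a linear nu-SVR is fitted at nu in {0.25, 0.5, 0.75},
#' the lowest-RMSE fit is kept and negative coefficients are clipped.
#' Either way the coefficients are renormalised to the simplex.
#'
#' @param mixture genes x samples bulk matrix (linear scale); rownames
#'   must contain the signature genes.
#' @param signature genes x cell-types non-negative reference matrix.
#' @param method `"nnls"` (default) or `"nu-svr"`.
#' @return object of class `fraction_estimate`: list with `fractions`
#'   (cell types x samples, columns on the simplex), `rmse` per sample,
#'   and the method used.
#' @export
deconvolve_fractions <- function(mixture, signature,
                                 method = c("nnls", "nu-svr")) {
  method <- match.arg(method)
  if (is.null(dim(signature)) || ncol(signature) < 2L)
    stop("signature must have >= 2 cell types")
  sig <- unclass(as.matrix(signature))
  if (any(colSums(abs(sig)) == 0)) stop("signature has an all-zero column")
  genes <- rownames(sig)
  if (is.null(genes) || !all(genes %in% rownames(mixture)))
    stop("signature genes must be a subset of the mixture genes")
  M <- mixture[genes, , drop = FALSE]
  k <- ncol(sig)

  solve_one <- function(y) {
    if (method == "nnls") {
      coefs <- pracma::lsqnonneg(sig, y)$x
    } else {
      fits <- lapply(c(0.25, 0.5, 0.75), function(nu) {
        f <- e1071::svm(x = sig, y = y, type = "nu-regression",
                        kernel = "linear", nu = nu, scale = FALSE)
        w <- drop(t(f$coefs) %*% f$SV)
        w[w < 0] <- 0
        list(w = w, rmse = sqrt(mean((drop(sig %*% w) - y)^2)))
      })
      coefs <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rmse"))]]$w
    }
    rmse <- sqrt(mean((drop(sig %*% coefs) - y)^2))
    s <- sum(coefs)
    frac <- if (s > 0) coefs / s else rep(1 / k, k)
    c(frac, rmse)
  }

  res <- apply(M, 2, solve_one)
  fractions <- res[seq_len(k), , drop = FALSE]
  rownames(fractions) <- colnames(sig)
  colnames(fractions) <- colnames(M)
  structure(list(fractions = fractions,
                 rmse = stats::setNames(res[k + 1L, ], colnames(M)),
                 method = method),
            class = "fraction_estimate")
}

#' @export
print.fraction_estimate <- function(x, ...) {
  cat("Immune-cell fraction estimates (", x$method, "): ",
      ncol(x$fractions), " samples x ", nrow(x$fractions),
      " cell types\n", sep = "")
  cat("  mean fractions:",
      paste(sprintf("%s=%.2f", rownames(x$fractions),
                    rowMeans(x$fractions)), collapse = ", "), "\n")
  invisible(x)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' rho is the Pearson correlation of midranks (ties averaged); the
#' two-sided p-value uses `t = rho * sqrt((n - 2) / (1 - rho^2))` with
#' `n - 2` degrees of freedom.  For small samples (`n` <= 10) an exact
#' permutation p-value can be requested instead.  A constant input
#' vector leaves rho undefined (`NA`, with a warning) and p = 1.
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @param exact use the exact permutation distribution (only without
#'   ties and for n <= 10; otherwise falls back to the approximation).
#' @return list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n || n < 3L) stop("x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p = 1))
  }
  rho <- cor(rank(x), rank(y))
  if (exact && n <= 10L && !anyDuplicated(x) && !anyDuplicated(y)) {
    p <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
    return(list(rho = rho, p = p))
  }
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tt), df = n - 2))
}

.signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Correlate candidate-gene expression with immune-cell fractions
#'
#' One row per (gene, cell type) pair with Spearman rho, p-value and
#' significance stars, suitable for a lollipop-style report.
#'
#' @param expr genes x samples expression matrix.
#' @param fractions a `fraction_estimate` (or cell types x samples
#'   matrix) over the same samples.
#' @param genes genes to correlate (default: all rows of `expr`).
#' @return data.frame with `gene`, `cell_type`, `rho`, `p`, `stars`,
#'   sorted within gene by descending |rho|.
#' @export
correlate_gene_fractions <- function(expr, fractions, genes = rownames(expr)) {
  fr <- if (inherits(fractions, "fraction_estimate")) fractions$fractions
        else as.matrix(fractions)
  shared <- intersect(colnames(expr), colnames(fr))
  if (length(shared) < 3L)
    stop("expression and fractions share fewer than 3 samples")
  if (length(shared) < ncol(expr) || length(shared) < ncol(fr))
    stop("sample ids of expression and fractions do not match")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("genes not in expression matrix: ",
         paste(head(missing, 5), collapse = ", "))
  out <- do.call(rbind, lapply(genes, function(g) {
    res <- lapply(rownames(fr), function(ct)
      spearman_cor(expr[g, shared], fr[ct, shared]))
    data.frame(gene = g, cell_type = rownames(fr),
               rho = vapply(res, `[[`, numeric(1), "rho"),
               p = vapply(res, `[[`, numeric(1), "p"),
               stringsAsFactors = FALSE)
  }))
  out$stars <- .signif_stars(out$p)
  out <- out[order(out$gene, -abs(out$rho)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
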