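#' Write an expression matrix as TSV
#'
#' First column `gene_id`, then one column per sample; duplicated gene
#' ids are written as separate rows.
#'
#' @param matrix genes x samples numeric matrix.
#' @param path output file.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample-annotation table as TSV
#'
#' @param labels data.frame with `sample_id`, `class`, `batch`, `split`.
#' @param path output file.
#' @export
write_labels <- function(labels, path) {
  write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a typed analysis table
#'
#' Parses one of the TSV formats the workflow exchanges and validates
#' its structure.  Duplicate sample ids are rejected everywhere;
#' duplicate gene ids are allowed only for expression matrices.
#'
#' @param path TSV file with a header row.
#' @param kind one of `"expression"` (gene_id + numeric sample
#'   columns), `"labels"` (sample_id/class/batch\[/split\]),
#'   `"signature"` (gene_id + non-negative cell-type columns) or
#'   `"weights"` (gene id + per-model numeric columns, optional
#'   `Overall` column that must equal the row sums).
#' @return for `expression`/`signature`: a numeric matrix; for
#'   `labels`: a data.frame; for `weights`: a `weight_table` built from
#'   the per-model columns.
#' @export
load_table <- function(path, kind = c("expression", "labels", "signature",
                                      "weights")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed table (fewer than 2 columns): ", path)

  if (kind == "labels") {
    need <- c("sample_id", "class", "batch")
    if (!all(need %in% names(df)))
      stop("labels file must have columns ", paste(need, collapse = ", "))
    if (anyDuplicated(df$sample_id))
      stop("duplicate sample id(s): ",
           df$sample_id[duplicated(df$sample_id)][1])
    bad <- setdiff(unique(df$class), c("control", "case"))
    if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
    df$class <- factor(df$class, levels = c("control", "case"))
    if (!"split" %in% names(df)) df$split <- NA_character_
    return(df)
  }

  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric value column '", names(df)[-1][bad], "' in ", path)
  }
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id(s) in header of ", path)
  rownames(m) <- ids

  if (kind == "expression") return(m)

  if (anyDuplicated(ids))
    stop("duplicate gene id(s) not allowed for kind '", kind, "'")
  if (kind == "signature") {
    if (ncol(m) < 2L) stop("signature needs >= 2 cell types")
    if (any(m < 0)) stop("signature values must be non-negative")
    if (any(colSums(m) == 0)) stop("signature has an all-zero column")
    class(m) <- c("signature_matrix", class(m))
    return(m)
  }

  ## weights: optional Overall column checked against the row sums
  has_overall <- tolower(colnames(m)) %in% c("overall", "overall_weights",
                                             "overall weights")
  w <- m[, !has_overall, drop = FALSE]
  if (any(has_overall)) {
    ov <- m[, which(has_overall)[1]]
    if (max(abs(rowSums(w) - ov)) > 0.005 * ncol(w))
      stop("Overall column disagrees with the row sums in ", path)
  }
  normalize_weight_table(w, col_max = rep(1, ncol(w)), n_models = ncol(w))
}

#' Read an expression matrix from TSV
#'
#' @param path TSV written by [write_expression()].
#' @return numeric matrix (duplicate gene ids preserved).
#' @export
read_expression <- function(path) load_table(path, "expression")

#' Read a sample-annotation table from TSV
#'
#' @param path TSV written by [write_labels()].
#' @return validated data.frame.
#' @export
read_labels <- function(path) load_table(path, "labels")
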