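#' Construct an expression matrix container
#'
#' Wraps a genes x samples numeric matrix with a declared value kind:
#' `"counts"` for non-negative normalized counts (scored with the Poisson
#' kernel by default) or `"continuous"` for log-scale values (Gaussian
#' kernel).
#'
#' @param values Numeric matrix, genes in rows, samples in columns; dimnames
#'   supply gene and sample identifiers unless given explicitly.
#' @param gene_ids,sample_ids Optional identifier vectors overriding
#'   dimnames.
#' @param value_kind `"counts"` or `"continuous"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              value_kind = c("counts", "continuous")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  gene_ids <- trimws(as.character(gene_ids))
  sample_ids <- trimws(as.character(sample_ids))
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 genes and 2 samples")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier length does not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (!all(is.finite(values))) stop("all expression values must be finite")
  if (value_kind == "counts" && any(values < 0))
    stop("counts mode requires non-negative values")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, value_kind = value_kind),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", x$value_kind, ")\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expected dialect: header row of sample identifiers, first column of gene
#' identifiers, tab-separated numeric body.
#'
#' @param path Path to a TSV file.
#' @inheritParams expression_matrix
#' @return An `expression_matrix`.
#' @export
read_expression_tsv <- function(path, value_kind = c("counts", "continuous")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expression TSV needs a gene column and >= 2 samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, value_kind = match.arg(value_kind))
}

#' Write an expression or score matrix as TSV
#'
#' @param m Numeric matrix with dimnames, or an `expression_matrix`.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  if (inherits(m, "expression_matrix")) m <- m$values
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
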