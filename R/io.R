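#' Read an expression matrix from TSV
#'
#' Expected layout: header row of gene identifiers, first column sample
#' identifiers, remaining columns numeric linear-scale expression (samples
#' in rows, genes in columns).
#'
#' @param path TSV file path.
#' @return Numeric matrix with sample rownames and gene colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("Expression TSV needs a sample column plus genes: ",
                          path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("Non-numeric expression values in ", path)
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a samples-by-sets (or genes) matrix as TSV
#'
#' First column `sample_id`, then one column per matrix column. Missing
#' values are serialized as empty fields, never as 0 or 1.
#'
#' @param m Matrix with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a reference profile TSV
#'
#' Accepts either a two-column file (gene, value) giving one profile, or a
#' three-column file (gene, t, t_bar) giving both the matched-tissue and
#' cross-tissue profiles at once.
#'
#' @param path TSV file path with header.
#' @return For two columns, a named numeric vector. For three, a list
#'   with named vectors `t` and `t_bar`.
#' @export
read_reference_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 2L) {
    return(stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]])))
  }
  if (ncol(df) == 3L) {
    genes <- as.character(df[[1L]])
    return(list(t = stats::setNames(as.numeric(df[[2L]]), genes),
                t_bar = stats::setNames(as.numeric(df[[3L]]), genes)))
  }
  stop("Reference TSV must have 2 (gene, value) or 3 (gene, t, t_bar) ",
       "columns: ", path)
}

write_reference_tsv <- function(v, path, value_col = "value") {
  df <- data.frame(gene = names(v), value = as.numeric(v),
                   stringsAsFactors = FALSE)
  names(df)[2L] <- value_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
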