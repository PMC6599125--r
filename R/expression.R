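#' Expression matrix with a declared unit
#'
#' A genes-by-cells matrix of non-negative expression values carrying an
#' explicit unit tag, so that log handling downstream can refuse to
#' double-transform.  Units are \code{"CPM"} (counts per million reads),
#' \code{"UMI"} (molecule counts, possibly library-size normalized),
#' \code{"log2CPM1"} (log2(CPM+1)) and \code{"log2norm"} (log2 of normalized
#' counts + 1).
#'
#' @param values numeric matrix, genes as rows (rownames = gene ids), cells as
#'   columns (colnames = cell ids)
#' @param unit one of \code{"CPM"}, \code{"UMI"}, \code{"log2CPM1"},
#'   \code{"log2norm"}
#' @return an \code{expr_matrix} object
#' @export
expression_matrix <- function(values, unit = c("CPM", "UMI", "log2CPM1", "log2norm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and cell ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative expression value at gene '%s', cell '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  structure(list(values = values, unit = unit), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, unit = %s\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression table from a delimited file
#'
#' Expects genes as rows (first column gene ids), cells as columns (header row
#' of cell ids), numeric body.  The file is read as-is: CPM / UMI inputs are
#' not transformed.
#'
#' @param path TSV/CSV path (delimiter inferred from extension, default tab)
#' @param unit declared unit of the stored values
#' @export
read_expression_matrix <- function(path, unit = "CPM") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  expression_matrix(m, unit = unit)
}

#' Write an expression matrix to TSV
#' @param x expr_matrix
#' @param path output path
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_stable(df, path)
}

#' log2(x + 1) transform of an expression matrix
#'
#' Applies the pseudocount-1 log2 transform used throughout the pipeline.
#' Refuses already-log units so the transform cannot be applied twice.
#'
#' @param m expr_matrix in CPM or UMI units
#' @return expr_matrix in log2 units
#' @export
log_transform_expression <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit %in% c("log2CPM1", "log2norm"))
    stop("expression is already log-transformed (unit = ", m$unit, ")")
  out_unit <- if (m$unit == "CPM") "log2CPM1" else "log2norm"
  expression_matrix(log2(m$values + 1), unit = out_unit)
}
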