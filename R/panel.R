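#' Cell-type profile panel
#'
#' The unit of analysis for the type-level screens: per-type mean log
#' expression and mean transformed property values, plus the class label of
#' each type.
#'
#' @param expr genes x types numeric matrix of mean log2 expression
#' @param props types x properties numeric matrix (NA = property unavailable
#'   for that type)
#' @param class named character vector (\code{"excitatory"} /
#'   \code{"inhibitory"}), one entry per type
#' @param prop_meta data frame with columns \code{property}, \code{family};
#'   defaults to all-"ephys"
#' @param pairs optional data frame \code{(gene, property)} recording which
#'   gene each synthetic property column was generated from
#' @return a \code{ct_panel} object
#' @export
ct_panel <- function(expr, props, class, prop_meta = NULL, pairs = NULL) {
  stopifnot(is.matrix(expr), is.matrix(props))
  types <- colnames(expr)
  if (!identical(types, rownames(props)))
    stop("type ids of `expr` columns and `props` rows must match")
  if (!identical(sort(types), sort(names(class))))
    stop("`class` must be named by type id")
  class <- class[types]
  if (!all(class %in% c("excitatory", "inhibitory")))
    stop("class labels must be 'excitatory' or 'inhibitory'")
  if (is.null(prop_meta))
    prop_meta <- data.frame(property = colnames(props), family = "ephys",
                            stringsAsFactors = FALSE)
  structure(list(expr = expr, props = props, class = class,
                 prop_meta = prop_meta, pairs = pairs),
            class = "ct_panel")
}

#' @export
print.ct_panel <- function(x, ...) {
  cat(sprintf("<ct_panel> %d genes x %d types (%d exc / %d inh), %d properties\n",
              nrow(x$expr), ncol(x$expr),
              sum(x$class == "excitatory"), sum(x$class == "inhibitory"),
              ncol(x$props)))
  invisible(x)
}

#' Summarize cell-level data to cell-type profiles
#'
#' Computes, for each retained cell type, the arithmetic mean of
#' log-expression per gene (mean of logs, not log of means) over its RNA-seq
#' members and the mean of each transformed property over members with a
#' non-missing value.  A property with zero contributing cells in a type is
#' recorded as missing, never as zero.
#'
#' @param m log-transformed \code{expr_matrix} (cell-level)
#' @param props transformed property table (\code{cell_id} + property columns)
#' @param types output of [assign_cell_types()]
#' @param analysis which retention flag to honour (\code{"ephys"} uses the
#'   ephys member lists, \code{"morph"} the morphology ones)
#' @param prop_meta property metadata passed through to the panel
#' @return a [ct_panel()]
#' @export
summarize_to_cell_types <- function(m, props, types, analysis = c("ephys", "morph"),
                                    prop_meta = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$unit %in% c("log2CPM1", "log2norm"))
    stop("expression must be log-transformed before summarization")
  analysis <- match.arg(analysis)
  keep <- if (analysis == "ephys") types$retained_ephys else types$retained_morph
  types <- types[keep, , drop = FALSE]
  memb <- attr(types, "members")
  prop_cols <- setdiff(names(props), c("cell_id", "vm_for_sag", "resting_potential"))

  expr_out <- matrix(NA_real_, nrow(m$values), nrow(types),
                     dimnames = list(rownames(m$values), types$type_id))
  prop_out <- matrix(NA_real_, nrow(types), length(prop_cols),
                     dimnames = list(types$type_id, prop_cols))
  for (i in seq_len(nrow(types))) {
    tid <- types$type_id[i]
    rn <- memb[[tid]]$rnaseq
    if (length(rn) == 0) stop("type ", tid, " has no RNA-seq members")
    expr_out[, i] <- rowMeans(m$values[, rn, drop = FALSE])
    pm <- memb[[tid]][[analysis]]
    sub <- props[props$cell_id %in% pm, prop_cols, drop = FALSE]
    prop_out[i, ] <- vapply(sub, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
  }
  cls <- stats::setNames(types$class_label, types$type_id)
  ct_panel(expr_out, prop_out, cls, prop_meta = prop_meta)
}

#' Filter genes by type-level expression
#'
#' Keeps genes whose mean log2(CPM+1) expression reaches \code{min_level} in
#' at least \code{min_types} cell types; with the defaults that is the
#' "1 CPM or higher in at least ten types" rule (log2(1+1) = 1).
#'
#' @param panel a [ct_panel()] in log2(CPM+1) units
#' @param min_level log2-scale threshold
#' @param min_types minimum number of types at or above the threshold
#' @return character vector of retained gene ids
#' @export
filter_genes_by_expression <- function(panel, min_level = 1.0, min_types = 10) {
  stopifnot(inherits(panel, "ct_panel"))
  if (min_types > ncol(panel$expr))
    stop("min_types (", min_types, ") exceeds number of types (",
         ncol(panel$expr), ")")
  n_above <- rowSums(panel$expr >= min_level)
  keep <- rownames(panel$expr)[n_above >= min_types]
  nc_log(sprintf("filter_genes_by_expression: %d of %d genes retained (%.1f%%)",
                 length(keep), nrow(panel$expr),
                 100 * length(keep) / max(1, nrow(panel$expr))))
  keep
}

#' Write / read a profile panel as a pair of TSVs
#' @param panel a [ct_panel()]
#' @param dir output directory (created if needed)
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_stable(data.frame(gene_id = rownames(panel$expr), panel$expr,
                              check.names = FALSE), file.path(dir, "expr.tsv"))
  write_tsv_stable(data.frame(type_id = rownames(panel$props),
                              class_label = panel$class[rownames(panel$props)],
                              panel$props, check.names = FALSE),
                   file.path(dir, "props.tsv"))
  write_tsv_stable(panel$prop_meta, file.path(dir, "prop_meta.tsv"))
  if (!is.null(panel$pairs))
    write_tsv_stable(panel$pairs, file.path(dir, "pairs.tsv"))
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  ed <- read_tsv_plain(file.path(dir, "expr.tsv"))
  expr <- as.matrix(ed[, -1, drop = FALSE])
  rownames(expr) <- ed[[1]]
  pd <- read_tsv_plain(file.path(dir, "props.tsv"))
  props <- as.matrix(pd[, -(1:2), drop = FALSE])
  rownames(props) <- pd[[1]]
  cls <- stats::setNames(pd[[2]], pd[[1]])
  meta <- read_tsv_plain(file.path(dir, "prop_meta.tsv"))
  pairs_path <- file.path(dir, "pairs.tsv")
  pairs <- if (file.exists(pairs_path)) read_tsv_plain(pairs_path) else NULL
  ct_panel(expr, props, cls, prop_meta = meta, pairs = pairs)
}
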