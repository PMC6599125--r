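#' Normalize a PatchSeq counts matrix
#'
#' Library size is computed over protein-coding genes only (PatchSeq cells
#' vary strongly in mitochondrial / non-coding content).  UMI protocols are
#' scaled to a total of 2000 molecules per cell, read-based protocols to
#' counts per million; both are then log2(x+1)-transformed.  Cells with zero
#' protein-coding counts are dropped with a warning.  Re-normalizing an
#' already-normalized matrix is an error.
#'
#' @param counts genes x cells matrix of raw counts
#' @param protocol \code{"UMI"} or \code{"reads"}
#' @param protein_coding character vector of protein-coding gene ids
#' @return genes x cells matrix of normalized log2 expression with
#'   attributes \code{unit} and \code{normalized}
#' @export
normalize_patchseq <- function(counts, protocol = c("UMI", "reads"),
                               protein_coding) {
  protocol <- match.arg(protocol)
  if (isTRUE(attr(counts, "normalized")))
    stop("matrix is already normalized; refusing to normalize twice")
  if (any(counts < 0)) stop("negative counts")
  pc <- intersect(protein_coding, rownames(counts))
  if (length(pc) == 0) stop("no protein-coding genes found in the matrix")
  lib <- colSums(counts[pc, , drop = FALSE])
  drop <- lib == 0
  if (any(drop)) {
    warning(sum(drop), " cells with zero protein-coding counts dropped")
    counts <- counts[, !drop, drop = FALSE]
    lib <- lib[!drop]
  }
  target <- if (protocol == "UMI") 2000 else 1e6
  norm <- sweep(counts, 2, lib / target, "/")
  out <- log2(norm + 1)
  attr(out, "unit") <- if (protocol == "UMI") "log2norm" else "log2CPM1"
  attr(out, "normalized") <- TRUE
  out
}

#' Per-cell transcriptome quality score
#'
#' Contract: the score increases with expression of "on" markers (genes every
#' cell of the target population should express) and decreases with "off"
#' markers (contamination indicators, e.g. glial transcripts).  Implemented
#' as mean(on) - mean(off) on normalized log expression, min-max rescaled to
#' [0, 1] within the dataset.  The scoring function is deliberately simple
#' and pluggable; any monotone contamination-sensitive score can stand in.
#'
#' @param norm normalized log-expression matrix (genes x cells)
#' @param on_markers,off_markers marker gene sets
#' @return numeric vector of scores in [0, 1], one per cell
#' @export
compute_quality_score <- function(norm, on_markers, off_markers) {
  on <- intersect(on_markers, rownames(norm))
  off <- intersect(off_markers, rownames(norm))
  if (length(on) == 0 || length(off) == 0)
    stop("marker sets do not overlap the gene universe")
  raw <- colMeans(norm[on, , drop = FALSE]) - colMeans(norm[off, , drop = FALSE])
  rng <- range(raw)
  if (diff(rng) == 0) return(stats::setNames(rep(0.5, length(raw)), colnames(norm)))
  stats::setNames((raw - rng[1]) / diff(rng), colnames(norm))
}

#' Map cells to a reference atlas by nearest centroid
#'
#' Computes, over the highly variable genes shared between the cells and the
#' atlas, the Spearman correlation of every cell to every cluster centroid
#' and assigns each cell to its best-correlated cluster; the cluster is then
#' rolled up to its subclass.  Cells with constant expression over the
#' shared genes are left unassigned with a warning.  Ties are broken by
#' cluster id order and flagged.
#'
#' @param norm normalized log-expression matrix (genes x cells)
#' @param atlas list with \code{centroids} (genes x clusters matrix),
#'   \code{cluster_subclass} (named character vector cluster -> subclass) and
#'   \code{hvgs} (character vector)
#' @param min_shared minimum number of shared HVGs required
#' @return data frame with \code{cell_id}, \code{cluster}, \code{subclass},
#'   \code{rho}, \code{tie}; the full correlation matrix is attached as
#'   attribute \code{"correlations"}
#' @export
map_cells_to_atlas <- function(norm, atlas, min_shared = 50) {
  shared <- intersect(intersect(atlas$hvgs, rownames(norm)),
                      rownames(atlas$centroids))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " HVGs shared with the atlas (need >= ",
         min_shared, ")")
  X <- norm[shared, , drop = FALSE]
  Cm <- atlas$centroids[shared, , drop = FALSE]
  clusters <- colnames(Cm)[order(colnames(Cm))]
  Cm <- Cm[, clusters, drop = FALSE]
  rx <- apply(X, 2, rank)
  rc <- apply(Cm, 2, rank)
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  cors <- suppressWarnings(stats::cor(rx, rc))  # Pearson on average ranks = Spearman
  assign_one <- function(i) {
    if (const[i]) return(list(cluster = NA_character_, rho = NA_real_, tie = FALSE))
    v <- cors[i, ]
    best <- max(v)
    hits <- which(v >= best - 1e-12)
    list(cluster = clusters[hits[1]], rho = best, tie = length(hits) > 1)
  }
  res <- lapply(seq_len(ncol(X)), assign_one)
  if (any(const)) warning(sum(const), " cells with constant expression left unassigned")
  cluster <- vapply(res, `[[`, character(1), "cluster")
  out <- data.frame(cell_id = colnames(X),
                    cluster = cluster,
                    subclass = unname(atlas$cluster_subclass[cluster]),
                    rho = vapply(res, `[[`, numeric(1), "rho"),
                    tie = vapply(res, `[[`, logical(1), "tie"),
                    stringsAsFactors = FALSE)
  attr(out, "correlations") <- cors
  out
}

#' Rank genes by excess variance within one cell type
#'
#' A mean-variance-trend surrogate for per-type highly-variable-gene
#' selection: the technical trend is a running median of variance against
#' mean log expression, the biological component is total minus trend, and
#' genes are ranked by it in descending order.  Zero-variance genes are
#' never selected.
#'
#' @param norm normalized log-expression matrix for cells of one type
#' @param n_top number of genes to return
#' @param min_cells minimum cells required
#' @param span fraction of genes in the running-median window
#' @return character vector of gene ids, ranked, length <= n_top
#' @export
select_hvgs_per_type <- function(norm, n_top = 250, min_cells = 20, span = 0.3) {
  if (ncol(norm) < min_cells)
    stop("only ", ncol(norm), " cells; need >= ", min_cells)
  mu <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  keep <- v > 0
  if (!any(keep)) return(character(0))
  mu <- mu[keep]; v <- v[keep]
  o <- order(mu)
  k <- max(3L, as.integer(span * length(mu)))
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, length(mu) - (1 - length(mu) %% 2))
  trend_sorted <- stats::runmed(v[o], k = k, endrule = "median")
  trend <- numeric(length(mu))
  trend[o] <- trend_sorted
  bio <- v - trend
  genes <- names(mu)[order(-bio, names(mu))]
  utils::head(genes, n_top)
}

#' Gate (gene, type, dataset) groups for the mixed-model screen
#'
#' A gene is tested only if it is highly variable in at least one cell type
#' in at least \code{min_datasets} datasets.  A (gene, type, dataset) group
#' contributes only if the gene is detected in at least \code{min_frac} of
#' its cells and in at least \code{min_cells} cells.
#'
#' @param hvg_sets data frame \code{(dataset, type, gene)} listing per-type
#'   HVG membership
#' @param detection data frame \code{(dataset, type, gene, n_cells,
#'   n_detected)}
#' @param min_datasets,min_frac,min_cells gating thresholds
#' @return list with \code{genes} (tested genes) and \code{groups} (retained
#'   (gene, type, dataset) rows of \code{detection})
#' @export
gate_gene_type_pairs <- function(hvg_sets, detection, min_datasets = 2,
                                 min_frac = 1 / 3, min_cells = 5) {
  per_gene <- tapply(hvg_sets$dataset, hvg_sets$gene,
                     function(d) length(unique(d)))
  tested_genes <- names(per_gene)[per_gene >= min_datasets]
  keep <- detection$gene %in% tested_genes &
    detection$n_detected >= min_cells &
    detection$n_detected / detection$n_cells >= min_frac
  groups <- detection[keep, , drop = FALSE]
  rownames(groups) <- NULL
  list(genes = sort(tested_genes), groups = groups)
}

#' Quality-weighted mixed-effects test for one gene x property pair
#'
#' Fits, by maximum likelihood, a linear mixed model with the cell-level
#' log2 expression of the gene as fixed effect and a random intercept for
#' every (dataset x cell type) group, using per-cell quality scores --
#' normalized so each dataset's mean weight is 1 -- as regression weights.
#' Significance of the expression term comes from a likelihood-ratio test
#' against the model without it (chi-square, 1 df).
#'
#' @param df data frame with columns \code{expr} (log2 normalized
#'   expression), \code{prop}, \code{dataset}, \code{subclass}, \code{w}
#'   (quality in [0,1])
#' @param min_groups,min_cells minimum (dataset x subclass) groups / cells
#' @return list of class \code{mixed_result}: \code{beta}, \code{se},
#'   \code{lrt_stat}, \code{p}, \code{n_cells}, \code{n_groups},
#'   \code{converged}
#' @export
fit_mixed_gene_property <- function(df, min_groups = 2, min_cells = 20) {
  need <- c("expr", "prop", "dataset", "subclass", "w")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- df[stats::complete.cases(df[, need]), , drop = FALSE]
  df$grp <- interaction(df$dataset, df$subclass, drop = TRUE)
  if (nlevels(df$grp) < min_groups)
    stop("fewer than ", min_groups, " (dataset x subclass) groups")
  if (nrow(df) < min_cells) stop("fewer than ", min_cells, " cells")
  mw <- tapply(df$w, df$dataset, mean)
  df$w_norm <- df$w / as.numeric(mw[as.character(df$dataset)])
  # a min-max-scaled quality score can be exactly 0 for the worst cell of a
  # dataset; a zero regression weight degenerates the ML objective
  df$w_norm <- pmax(df$w_norm, 1e-6)

  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  converged <- TRUE
  full <- withCallingHandlers(
    lme4::lmer(prop ~ expr + (1 | grp), data = df, weights = w_norm,
               REML = FALSE, control = ctrl),
    warning = function(w) { converged <<- FALSE; invokeRestart("muffleWarning") })
  null <- withCallingHandlers(
    lme4::lmer(prop ~ 1 + (1 | grp), data = df, weights = w_norm,
               REML = FALSE, control = ctrl),
    warning = function(w) { converged <<- FALSE; invokeRestart("muffleWarning") })
  lrt <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                       as.numeric(stats::logLik(null))))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  fe <- lme4::fixef(full)
  se <- sqrt(diag(as.matrix(stats::vcov(full))))
  structure(list(beta = unname(fe[["expr"]]), se = unname(se[2]),
                 lrt_stat = lrt, p = p, n_cells = nrow(df),
                 n_groups = nlevels(df$grp), converged = converged),
            class = "mixed_result")
}

#' Detection statistics per (dataset, type, gene)
#'
#' @param norm normalized log-expression matrix of one dataset
#' @param subclass named character vector cell -> subclass
#' @param genes genes to tabulate (default all)
#' @param dataset_id label for the output
#' @return data frame \code{(dataset, type, gene, n_cells, n_detected)}
#' @export
detection_stats <- function(norm, subclass, genes = rownames(norm),
                            dataset_id = "ds") {
  subclass <- subclass[colnames(norm)]
  out <- lapply(unique(subclass[!is.na(subclass)]), function(tp) {
    cells <- names(subclass)[!is.na(subclass) & subclass == tp]
    sub <- norm[genes, cells, drop = FALSE]
    data.frame(dataset = dataset_id, type = tp, gene = genes,
               n_cells = length(cells),
               n_detected = rowSums(sub > 0),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' PatchSeq screen and concordance with a type-level screen
#'
#' Runs the quality-weighted mixed model for every gated gene x property
#' pair across datasets, applies BH-FDR per property (non-converged fits are
#' excluded from the family), and -- when a type-level screen table is
#' supplied -- reports per-property sign concordance among pairs significant
#' in both analyses.
#'
#' @param cells data frame with one row per cell: \code{cell_id},
#'   \code{dataset}, \code{subclass}, \code{w}, one column per property and
#'   the normalized expression accessed through \code{expr_fun}
#' @param expr_fun function(gene) -> named numeric vector of normalized
#'   expression per cell_id
#' @param pairs data frame \code{(gene, property)} to test
#' @param groups gated groups from [gate_gene_type_pairs()]
#' @param aibs_fits optional type-level screen fits table (long format with
#'   \code{gene}, \code{property}, \code{model}, \code{beta}, \code{q})
#' @param fdr significance threshold for the concordance comparison
#' @return list with \code{results} (one row per pair with q) and
#'   \code{concordance} (per property, or NULL)
#' @export
patchseq_screen_and_concordance <- function(cells, expr_fun, pairs, groups,
                                            aibs_fits = NULL, fdr = 0.1) {
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene[i]; pr <- pairs$property[i]
    gk <- groups[groups$gene == g, c("dataset", "type")]
    keep <- paste(cells$dataset, cells$subclass) %in% paste(gk$dataset, gk$type)
    sub <- cells[keep, , drop = FALSE]
    ev <- expr_fun(g)
    df <- data.frame(expr = unname(ev[sub$cell_id]), prop = sub[[pr]],
                     dataset = sub$dataset, subclass = sub$subclass,
                     w = sub$w, stringsAsFactors = FALSE)
    fit <- tryCatch(fit_mixed_gene_property(df), error = function(e) NULL)
    res[[i]] <- data.frame(
      gene = g, property = pr,
      beta = if (is.null(fit)) NA_real_ else fit$beta,
      se = if (is.null(fit)) NA_real_ else fit$se,
      lrt_stat = if (is.null(fit)) NA_real_ else fit$lrt_stat,
      p = if (is.null(fit)) NA_real_ else fit$p,
      n_cells = if (is.null(fit)) 0L else fit$n_cells,
      n_groups = if (is.null(fit)) 0L else fit$n_groups,
      converged = if (is.null(fit)) FALSE else fit$converged,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  results$q <- NA_real_
  for (pr in unique(results$property)) {
    idx <- which(results$property == pr & results$converged & !is.na(results$p))
    if (length(idx) > 0) results$q[idx] <- bh_fdr(results$p[idx])
  }
  concordance <- NULL
  if (!is.null(aibs_fits)) {
    ref <- aibs_fits[aibs_fits$model == "conditional", ]
    m <- merge(results[!is.na(results$q) & results$q <= fdr, ],
               ref[!is.na(ref$q) & ref$q <= fdr, c("gene", "property", "beta", "q")],
               by = c("gene", "property"), suffixes = c("_ps", "_ref"))
    if (nrow(m) == 0) {
      concordance <- data.frame(property = character(0), n_both = integer(0),
                                n_concordant = integer(0),
                                concordance = numeric(0))
    } else {
      concordance <- do.call(rbind, lapply(split(m, m$property), function(s) {
        conc <- sign(s$beta_ps) == sign(s$beta_ref)
        data.frame(property = s$property[1], n_both = nrow(s),
                   n_concordant = sum(conc), concordance = mean(conc),
                   stringsAsFactors = FALSE)
      }))
      rownames(concordance) <- NULL
    }
  }
  list(results = results, concordance = concordance)
}
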