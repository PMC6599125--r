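default_config <- function() {
  list(
    seed = 1L,
    out_dir = "results/run",
    fdr_primary = 0.1,
    fdr_exclusion = 0.2,
    gene_filter = list(min_level = 1.0, min_types = 10L),
    cell_minima = list(ephys = 6L, morph = 3L),
    n_boot = 100L,
    gating = list(min_frac = 1 / 3, min_cells = 5L),
    hvg = list(atlas = 2000L, per_type = 250L),
    fdr_family = "model",
    simulate = list(panel = list(), paired = list(), patchseq = list()),
    stages = c("simulate", "summarize", "screen", "pca", "consistency")
  )
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills defaults, and rejects unknown keys
#' (suggesting the nearest known key).  The resolved configuration
#' re-validates to itself.
#'
#' @param path YAML file path, or a list to validate directly
#' @return resolved configuration list of class \code{nc_config}
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) unclass(path) else stop("`path` must be a file or list")
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown) > 0) {
    hints <- vapply(unknown, function(k) {
      d <- utils::adist(k, names(def))
      names(def)[which.min(d)]
    }, character(1))
    stop("unknown config keys: ",
         paste(sprintf("'%s' (did you mean '%s'?)", unknown, hints),
               collapse = ", "))
  }
  out <- utils::modifyList(def, cfg)
  if (out$fdr_primary <= 0 || out$fdr_exclusion <= 0 || out$n_boot <= 0)
    stop("thresholds must be positive")
  structure(out, class = "nc_config")
}

run_manifest <- function(cfg, stage_info, out_dir) {
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package = "neurocorr",
    version = as.character(utils::packageVersion("neurocorr")),
    r_version = R.version.string,
    seed = cfg$seed,
    thresholds = cfg[c("fdr_primary", "fdr_exclusion", "gene_filter",
                       "cell_minima", "n_boot", "gating", "hvg")],
    stages = stage_info,
    outputs = lapply(files, function(f)
      list(path = sub(paste0("^", out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages in dependency order: \code{simulate} (panel +
#' paired panels + PatchSeq data), \code{summarize}, \code{screen},
#' \code{pca}, \code{consistency}, \code{patchseq}.  Every stage derives its
#' own child seed from the global seed, writes TSV outputs under the output
#' directory, and the run closes with a JSON manifest recording thresholds,
#' seeds, versions and output checksums.  A rerun with an identical
#' configuration is byte-identical.
#'
#' @param config an \code{nc_config} (or path / list accepted by
#'   [validate_config()])
#' @param stages subset of stages to run; defaults to \code{config$stages}
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest
#' @export
run_pipeline <- function(config, stages = NULL) {
  cfg <- validate_config(config)
  stages <- stages %||% cfg$stages
  known <- c("simulate", "summarize", "screen", "pca", "consistency", "patchseq")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stages: ", paste(bad, collapse = ", "))
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  info <- list()

  if ("simulate" %in% stages) {
    s_seed <- derive_seed(cfg$seed, "simulate")
    res$sim <- do.call(simulate_celltype_panel,
                       utils::modifyList(list(seed = s_seed),
                                         cfg$simulate$panel))
    write_expression_matrix(res$sim$expr, file.path(out_dir, "sim_expr_cpm.tsv"))
    write_tsv_stable(res$sim$truth, file.path(out_dir, "sim_truth.tsv"))
    write_tsv_stable(res$sim$cells, file.path(out_dir, "sim_cells.tsv"))
    info$simulate <- list(seed = s_seed, n_genes = nrow(res$sim$truth))
  }
  if ("summarize" %in% stages) {
    if (is.null(res$sim)) stop("summarize requires the simulate stage")
    res$panel <- summarize_simulated_panel(res$sim)
    write_panel(res$panel, file.path(out_dir, "panel"))
    info$summarize <- list(n_types = ncol(res$panel$expr))
  }
  if ("screen" %in% stages) {
    if (is.null(res$panel)) stop("screen requires the summarize stage")
    res$screen <- screen(res$panel, fdr = cfg$fdr_primary,
                         fdr_family = cfg$fdr_family)
    write_tsv_stable(res$screen$fits, file.path(out_dir, "screen_fits.tsv"))
    write_tsv_stable(res$screen$calls, file.path(out_dir, "screen_calls.tsv"))
    write_tsv_stable(res$screen$counts, file.path(out_dir, "screen_counts.tsv"))
    info$screen <- list(n_pairs = nrow(res$screen$calls))
  }
  if ("pca" %in% stages) {
    if (is.null(res$panel)) stop("pca requires the summarize stage")
    n_props <- ncol(res$panel$props)
    use <- res$panel
    if (n_props > 12) {
      # synthetic panels carry one property per gene; a 12-property subset
      # is enough to exercise the decomposition
      keep <- colnames(use$props)[seq_len(12)]
      use <- ct_panel(use$expr, use$props[, keep, drop = FALSE], use$class,
                      prop_meta = use$prop_meta[use$prop_meta$property %in% keep, ])
    }
    res$pca <- fit_property_pca(use, "ephys")
    write_tsv_stable(data.frame(type_id = rownames(res$pca$scores),
                                res$pca$scores, check.names = FALSE),
                     file.path(out_dir, "pca_scores.tsv"))
    write_tsv_stable(data.frame(property = rownames(res$pca$loadings),
                                res$pca$loadings, check.names = FALSE),
                     file.path(out_dir, "pca_loadings.tsv"))
    info$pca <- list(variance_explained = res$pca$variance_explained)
  }
  if ("consistency" %in% stages) {
    c_seed <- derive_seed(cfg$seed, "consistency")
    paired <- do.call(simulate_paired_panels,
                      utils::modifyList(list(seed = c_seed),
                                        cfg$simulate$paired))
    sa_ind <- panel_slopes(paired$panel_a, model = "independent")
    sa_cond <- panel_slopes(paired$panel_a, model = "conditional")
    sb <- single_class_slopes(paired$panel_b)
    boot <- bootstrap_consistency(sa_cond, sb, n_boot = cfg$n_boot,
                                  seed = c_seed)
    cmp <- compare_model_consistency(sa_ind, sb, sa_cond, sb,
                                     n_boot = cfg$n_boot, seed = c_seed)
    res$consistency <- list(boot = boot, comparison = cmp)
    write_tsv_stable(data.frame(model = c("independent", "conditional"),
                                rho = c(cmp$rho_model1, cmp$rho_model2),
                                ci_low = c(NA, boot$ci_low),
                                ci_high = c(NA, boot$ci_high),
                                n_genes = boot$n_genes,
                                n_boot = boot$n_boot, seed = boot$seed),
                     file.path(out_dir, "consistency.tsv"))
    write_tsv_stable(data.frame(delta = cmp$delta, ci_low = cmp$ci_low,
                                ci_high = cmp$ci_high,
                                significant = cmp$significant),
                     file.path(out_dir, "model_comparison.tsv"))
    info$consistency <- list(seed = c_seed, rho = boot$rho)
  }
  if ("patchseq" %in% stages) {
    p_seed <- derive_seed(cfg$seed, "patchseq")
    ps <- do.call(simulate_patchseq,
                  utils::modifyList(list(seed = p_seed),
                                    cfg$simulate$patchseq))
    res$patchseq <- run_patchseq_stage(ps, cfg)
    write_tsv_stable(res$patchseq$results,
                     file.path(out_dir, "patchseq_results.tsv"))
    info$patchseq <- list(seed = p_seed,
                          n_tested = nrow(res$patchseq$results))
  }

  res$manifest <- run_manifest(cfg, info, out_dir)
  invisible(res)
}

# Normalization -> quality -> detection gating -> mixed-model screen over a
# simulated multi-dataset PatchSeq bundle, using true subclass labels.
run_patchseq_stage <- function(ps, cfg) {
  norm <- lapply(ps$datasets, function(d)
    normalize_patchseq(d$counts, d$protocol, ps$protein_coding))
  cells <- do.call(rbind, lapply(names(ps$datasets), function(nm) {
    d <- ps$datasets[[nm]]
    w <- compute_quality_score(norm[[nm]], ps$on_markers, ps$off_markers)
    df <- data.frame(cell_id = d$cells$cell_id, dataset = d$cells$dataset,
                     subclass = d$cells$subclass, w = unname(w[d$cells$cell_id]),
                     stringsAsFactors = FALSE)
    cbind(df, d$props[match(df$cell_id, d$props$cell_id), -1, drop = FALSE])
  }))
  sig_genes <- ps$pairs$gene
  detection <- do.call(rbind, lapply(names(ps$datasets), function(nm) {
    d <- ps$datasets[[nm]]
    detection_stats(norm[[nm]],
                    stats::setNames(d$cells$subclass, d$cells$cell_id),
                    genes = sig_genes, dataset_id = d$cells$dataset[1])
  }))
  hvg_sets <- do.call(rbind, lapply(names(ps$datasets), function(nm) {
    d <- ps$datasets[[nm]]
    by_type <- split(d$cells$cell_id, d$cells$subclass)
    do.call(rbind, lapply(names(by_type), function(tp) {
      cells_tp <- by_type[[tp]]
      if (length(cells_tp) < 5) return(NULL)
      hv <- select_hvgs_per_type(norm[[nm]][, cells_tp, drop = FALSE],
                                 n_top = cfg$hvg$per_type,
                                 min_cells = min(5, length(cells_tp)))
      data.frame(dataset = d$cells$dataset[1], type = tp, gene = hv,
                 stringsAsFactors = FALSE)
    }))
  }))
  gate <- gate_gene_type_pairs(hvg_sets, detection,
                               min_frac = cfg$gating$min_frac,
                               min_cells = cfg$gating$min_cells)
  pairs <- ps$pairs[ps$pairs$gene %in% gate$genes, , drop = FALSE]
  expr_all <- do.call(cbind, norm)
  expr_fun <- function(g) expr_all[g, ]
  out <- patchseq_screen_and_concordance(cells, expr_fun, pairs, gate$groups)
  out$gate <- gate
  out$cells <- cells
  out
}
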