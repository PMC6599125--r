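SCENARIOS <- c("null", "class_driven", "shared", "obscured", "interaction")

#' Simulate a cell-level panel with planted gene-property scenarios
#'
#' Generates a panel of cell types (default 14 excitatory / 34 inhibitory,
#' mirroring the composition of large Cre-line surveys of mouse visual
#' cortex) with one synthetic property per gene, planted according to one of
#' five scenarios:
#' \describe{
#'   \item{null}{no relationship (beta = 0, no class structure)}
#'   \item{class_driven}{no within-class slope; both the expression and the
#'     property are shifted between classes, producing a purely between-class
#'     marginal correlation}
#'   \item{shared}{the same nonzero slope in both classes, visible marginally}
#'   \item{obscured}{the same nonzero slope within classes, with a class
#'     offset on the property chosen so the marginal (pooled) covariance of
#'     the type-level values is exactly zero -- the Simpson's-paradox case}
#'   \item{interaction}{different slopes in the two classes}
#' }
#' Type-level latent log2 expression is \eqn{x_t = \mu + \delta 1[inh] +
#' N(0, \sigma_{type})}; the type-level property is \eqn{p_t = \alpha +
#' \beta_{class(t)} x_t + \gamma 1[inh] + N(0, \sigma_{noise})}.  Cell-level
#' values are drawn around the type means with sd \code{sigma_cell} so the
#' summarization stage is exercised, and expression is emitted on the CPM
#' scale (\eqn{2^x - 1}, floored at 0) so the log transform is exercised too.
#'
#' @param n_exc,n_inh numbers of excitatory / inhibitory types
#' @param genes_per_scenario named integer vector over the five scenarios
#' @param beta shared/obscured within-class slope
#' @param beta_exc,beta_inh interaction-scenario slopes
#' @param delta class expression shift (log2 units, inhibitory - excitatory)
#' @param gamma class property offset for the class-driven scenario
#' @param mu baseline log2 expression
#' @param alpha baseline property value
#' @param sigma_type between-type expression sd (log2 units)
#' @param sigma_noise type-level property noise sd
#' @param sigma_cell within-type cell-level sd (applied to both expression
#'   and property draws)
#' @param cells_per_type cells simulated per type
#' @param seed RNG seed; the generator is a pure function of seed + arguments
#' @return list with \code{expr} (cell-level [expression_matrix()], CPM),
#'   \code{props} (cell-level property table), \code{cells} (metadata),
#'   \code{grouping} (type grouping config), \code{truth} (per-gene scenario
#'   and parameters), \code{pairs} (gene -> property pairing)
#' @export
simulate_celltype_panel <- function(n_exc = 14, n_inh = 34,
                                    genes_per_scenario = c(null = 50,
                                                           class_driven = 50,
                                                           shared = 50,
                                                           obscured = 50,
                                                           interaction = 50),
                                    beta = 1, beta_exc = 1, beta_inh = -1,
                                    delta = 2, gamma = 2,
                                    mu = 5, alpha = 0,
                                    sigma_type = 1, sigma_noise = 0.5,
                                    sigma_cell = 0.25,
                                    cells_per_type = 5, seed = 1) {
  stopifnot(all(names(genes_per_scenario) %in% SCENARIOS),
            all(genes_per_scenario >= 0), cells_per_type >= 1)
  set.seed(seed)
  n_types <- n_exc + n_inh
  type_ids <- sprintf("t%02d", seq_len(n_types))
  cls <- c(rep("excitatory", n_exc), rep("inhibitory", n_inh))
  Cnum <- as.numeric(cls == "inhibitory")

  scen <- rep(names(genes_per_scenario), genes_per_scenario)
  n_genes <- length(scen)
  genes <- sprintf("g%04d", seq_len(n_genes))

  x_type <- matrix(NA_real_, n_genes, n_types, dimnames = list(genes, type_ids))
  p_type <- matrix(NA_real_, n_genes, n_types, dimnames = list(genes, type_ids))
  truth <- data.frame(gene = genes, scenario = scen,
                      beta_exc = 0, beta_inh = 0, delta = 0, gamma = 0,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_genes)) {
    s <- scen[i]
    b_e <- switch(s, shared = beta, obscured = beta, interaction = beta_exc, 0)
    b_i <- switch(s, shared = beta, obscured = beta, interaction = beta_inh, 0)
    d <- switch(s, class_driven = delta, shared = delta, obscured = delta, 0)
    x <- mu + d * Cnum + stats::rnorm(n_types, 0, sigma_type)
    g <- switch(s, class_driven = gamma, 0)
    if (s == "obscured") {
      # class property offset cancelling the empirical marginal covariance
      sxx <- sum((x - mean(x))^2)
      sxc <- sum((x - mean(x)) * (Cnum - mean(Cnum)))
      g <- -beta * sxx / sxc
    }
    b_vec <- ifelse(Cnum == 1, b_i, b_e)
    p_type[i, ] <- alpha + b_vec * x + g * Cnum +
      stats::rnorm(n_types, 0, sigma_noise)
    x_type[i, ] <- x
    truth$beta_exc[i] <- b_e; truth$beta_inh[i] <- b_i
    truth$delta[i] <- d; truth$gamma[i] <- g
  }

  n_cells <- n_types * cells_per_type
  cell_ids <- sprintf("c%05d", seq_len(n_cells))
  cell_type <- rep(type_ids, each = cells_per_type)
  t_idx <- rep(seq_len(n_types), each = cells_per_type)

  x_cell <- x_type[, t_idx, drop = FALSE] +
    matrix(stats::rnorm(n_genes * n_cells, 0, sigma_cell), n_genes, n_cells)
  x_cell[x_cell < 0] <- 0
  colnames(x_cell) <- cell_ids
  expr <- expression_matrix(2^x_cell - 1, unit = "CPM")

  p_cell <- t(p_type[, t_idx, drop = FALSE] +
                matrix(stats::rnorm(n_genes * n_cells, 0, sigma_cell),
                       n_genes, n_cells))
  colnames(p_cell) <- paste0("p_", genes)
  props <- data.frame(cell_id = cell_ids, p_cell, check.names = FALSE,
                      stringsAsFactors = FALSE)

  cells <- data.frame(cell_id = cell_ids, dataset_id = "sim",
                      cre_line = cell_type, layer = "L0",
                      class_label = cls[t_idx],
                      reporter_positive = TRUE, qc_pass = TRUE,
                      has_rnaseq = TRUE, has_ephys = TRUE, has_morph = TRUE,
                      stringsAsFactors = FALSE)
  grouping <- data.frame(type_id = type_ids, cre_line = type_ids,
                         layer = "L0", class_label = cls,
                         stringsAsFactors = FALSE)
  pairs <- data.frame(gene = genes, property = paste0("p_", genes),
                      stringsAsFactors = FALSE)
  list(expr = expr, props = props, cells = cells, grouping = grouping,
       truth = truth, pairs = pairs, seed = seed)
}

#' Summarize a simulated cell-level panel to a type-level profile panel
#'
#' Convenience wrapper running the standard pipeline (log transform, type
#' assignment, summarization) over [simulate_celltype_panel()] output.
#'
#' @param sim output of [simulate_celltype_panel()]
#' @param min_ephys minimum cells per type (simulated panels default to all
#'   cells carrying every modality)
#' @return a [ct_panel()] with the gene/property pairing attached
#' @export
summarize_simulated_panel <- function(sim, min_ephys = 1) {
  m <- log_transform_expression(sim$expr)
  types <- assign_cell_types(sim$cells, sim$grouping, min_ephys = min_ephys,
                             min_morph = 1)
  panel <- summarize_to_cell_types(m, sim$props, types, analysis = "ephys")
  panel$pairs <- sim$pairs
  panel
}

#' Simulate paired panels with a controlled slope correlation
#'
#' Builds two type-level panels whose per-gene true slopes are correlated at
#' \code{slope_correlation}: the first a two-class panel (optionally with a
#' per-gene class confound of sd \code{confound_sd} on the property and a
#' class expression shift \code{delta}), the second a single-class
#' (inhibitory-only) panel mirroring a literature-pooled reference of
#' non-projecting types.
#'
#' @param n_genes number of genes (each with its own property column)
#' @param slope_correlation target correlation of true slopes in [0, 1]
#' @param n_exc,n_inh panel-A composition
#' @param n_types_b number of (inhibitory) types in panel B
#' @param beta_sd sd of the true slope distribution
#' @param sigma_type between-type expression sd
#' @param sigma_noise_a,sigma_noise_b property noise per panel
#' @param mu baseline log2 expression
#' @param delta class expression shift in panel A (only active with
#'   \code{confound_sd > 0})
#' @param confound_sd sd of the per-gene class property offset in panel A
#' @param seed RNG seed
#' @return list with \code{panel_a}, \code{panel_b} ([ct_panel()]s) and
#'   \code{truth}
#' @export
simulate_paired_panels <- function(n_genes = 200, slope_correlation = 1,
                                   n_exc = 14, n_inh = 34, n_types_b = 19,
                                   beta_sd = 0.3, sigma_type = 1,
                                   sigma_noise_a = 0.1, sigma_noise_b = 0.1,
                                   mu = 5, delta = 2, confound_sd = 0,
                                   seed = 1) {
  stopifnot(slope_correlation >= 0, slope_correlation <= 1)
  set.seed(seed)
  r <- slope_correlation
  beta_a <- stats::rnorm(n_genes, 0, beta_sd)
  beta_b <- r * beta_a + sqrt(1 - r^2) * stats::rnorm(n_genes, 0, beta_sd)
  gamma <- if (confound_sd > 0) stats::rnorm(n_genes, 0, confound_sd)
           else rep(0, n_genes)
  d <- if (confound_sd > 0) delta else 0
  genes <- sprintf("g%04d", seq_len(n_genes))
  props <- paste0("p_", genes)

  nA <- n_exc + n_inh
  typesA <- sprintf("a%02d", seq_len(nA))
  clsA <- stats::setNames(c(rep("excitatory", n_exc), rep("inhibitory", n_inh)),
                          typesA)
  Cnum <- as.numeric(clsA == "inhibitory")
  exprA <- matrix(NA_real_, n_genes, nA, dimnames = list(genes, typesA))
  propA <- matrix(NA_real_, nA, n_genes, dimnames = list(typesA, props))
  typesB <- sprintf("b%02d", seq_len(n_types_b))
  clsB <- stats::setNames(rep("inhibitory", n_types_b), typesB)
  exprB <- matrix(NA_real_, n_genes, n_types_b, dimnames = list(genes, typesB))
  propB <- matrix(NA_real_, n_types_b, n_genes, dimnames = list(typesB, props))
  for (i in seq_len(n_genes)) {
    xA <- mu + d * Cnum + stats::rnorm(nA, 0, sigma_type)
    propA[, i] <- beta_a[i] * xA + gamma[i] * Cnum +
      stats::rnorm(nA, 0, sigma_noise_a)
    exprA[i, ] <- xA
    xB <- mu + stats::rnorm(n_types_b, 0, sigma_type)
    propB[, i] <- beta_b[i] * xB + stats::rnorm(n_types_b, 0, sigma_noise_b)
    exprB[i, ] <- xB
  }
  pairs <- data.frame(gene = genes, property = props, stringsAsFactors = FALSE)
  list(panel_a = ct_panel(exprA, propA, clsA, pairs = pairs),
       panel_b = ct_panel(exprB, propB, clsB, pairs = pairs),
       truth = data.frame(gene = genes, beta_a = beta_a, beta_b = beta_b,
                          gamma = gamma, stringsAsFactors = FALSE),
       seed = seed)
}

#' Simulate multi-dataset PatchSeq-like cells
#'
#' Generates per-dataset count matrices in which within-type latent
#' expression drives both the observed counts (via multinomial sampling with
#' quality-dependent thinning) and a per-gene property (property = group
#' offset + beta x latent + noise).  Each cell carries a true quality in
#' \code{quality_range}; low-quality cells lose counts (dropout) and gain
#' contamination ("off"-marker) counts.  Datasets use either a UMI or a
#' read-count protocol.
#'
#' @param n_datasets number of datasets
#' @param n_subclasses subclasses shared across datasets
#' @param cells_per_subclass cells per (dataset, subclass)
#' @param n_body background genes
#' @param n_signal genes carrying a property relationship
#' @param beta fixed-effect slope planted for every signal gene (property
#'   units per log2 unit)
#' @param sigma_x within-type latent expression sd for signal genes
#' @param sigma_prop property noise sd
#' @param n_on,n_off,n_noncoding marker and non-coding gene counts
#' @param protocols per-dataset protocol (\code{"UMI"}/\code{"reads"}),
#'   recycled
#' @param quality_range range of true cell quality
#' @param lib_umi,lib_reads library sizes per protocol
#' @param seed RNG seed
#' @return list with \code{datasets} (each: \code{counts}, \code{cells},
#'   \code{props}, \code{protocol}), \code{protein_coding},
#'   \code{on_markers}, \code{off_markers}, \code{truth}, \code{pairs}
#' @export
simulate_patchseq <- function(n_datasets = 5, n_subclasses = 6,
                              cells_per_subclass = 10,
                              n_body = 220, n_signal = 30, beta = -0.05,
                              sigma_x = 1.5, sigma_prop = 0.1,
                              n_on = 20, n_off = 20, n_noncoding = 10,
                              protocols = c("UMI", "UMI", "UMI", "reads", "reads"),
                              quality_range = c(0.4, 1),
                              lib_umi = 4000, lib_reads = 150000, seed = 1) {
  stopifnot(n_datasets >= 2)
  set.seed(seed)
  protocols <- rep_len(protocols, n_datasets)
  sig_genes <- sprintf("sig%03d", seq_len(n_signal))
  body_genes <- sprintf("body%03d", seq_len(n_body))
  on_markers <- sprintf("on%02d", seq_len(n_on))
  off_markers <- sprintf("off%02d", seq_len(n_off))
  nc_genes <- sprintf("nc%02d", seq_len(n_noncoding))
  genes <- c(sig_genes, body_genes, on_markers, off_markers, nc_genes)
  n_genes <- length(genes)
  protein_coding <- setdiff(genes, nc_genes)

  base <- stats::setNames(c(stats::runif(n_signal, 5, 7),
                            stats::runif(n_body, 0.5, 5),
                            stats::runif(n_on, 6, 8),
                            rep(6, n_off),
                            stats::runif(n_noncoding, 4, 6)), genes)
  # subclass expression offsets, shared across datasets
  sub_ids <- sprintf("sc%d", seq_len(n_subclasses))
  sub_off <- matrix(stats::rnorm(n_genes * n_subclasses, 0, 0.8),
                    n_genes, n_subclasses, dimnames = list(genes, sub_ids))
  sub_off[c(on_markers, off_markers), ] <- 0
  within_sd <- stats::setNames(rep(0.6, n_genes), genes)
  within_sd[sig_genes] <- sigma_x

  prop_names <- paste0("prop_", sig_genes)
  datasets <- vector("list", n_datasets)
  truth_cells <- list()
  for (ds in seq_len(n_datasets)) {
    ds_id <- sprintf("ds%d", ds)
    n_cells <- n_subclasses * cells_per_subclass
    cell_ids <- sprintf("%s_c%03d", ds_id, seq_len(n_cells))
    subclass <- rep(sub_ids, each = cells_per_subclass)
    qual <- stats::runif(n_cells, quality_range[1], quality_range[2])
    grp_off <- matrix(stats::rnorm(n_signal * n_subclasses, 0, 0.3),
                      n_signal, n_subclasses,
                      dimnames = list(sig_genes, sub_ids))
    lat <- base + sub_off[, match(subclass, sub_ids)] +
      matrix(stats::rnorm(n_genes * n_cells), n_genes, n_cells) * within_sd
    lat[lat < 0] <- 0
    colnames(lat) <- cell_ids

    wgt <- 2^lat
    wgt[on_markers, ] <- sweep(wgt[on_markers, , drop = FALSE], 2, qual, "*")
    wgt[off_markers, ] <- sweep(wgt[off_markers, , drop = FALSE], 2,
                                (1 - qual), "*")
    lib <- if (protocols[ds] == "UMI") lib_umi else lib_reads
    counts <- matrix(0L, n_genes, n_cells, dimnames = list(genes, cell_ids))
    for (cc in seq_len(n_cells)) {
      pr <- wgt[, cc] / sum(wgt[, cc])
      raw <- stats::rmultinom(1, size = lib, prob = pr)[, 1]
      counts[, cc] <- stats::rbinom(n_genes, raw, qual[cc])  # quality-tied thinning
    }

    # property measurement noise scales with each cell's realized
    # transcriptome-quality weight (variance proportional to 1 / weight),
    # the reliability structure a quality-weighted regression models
    norm_ds <- normalize_patchseq(counts, protocols[ds], protein_coding)
    w_score <- compute_quality_score(norm_ds, on_markers, off_markers)
    w_norm <- pmax(w_score / mean(w_score), 0.05)
    props <- matrix(NA_real_, n_cells, n_signal,
                    dimnames = list(cell_ids, prop_names))
    for (j in seq_len(n_signal)) {
      props[, j] <- grp_off[j, match(subclass, sub_ids)] +
        beta * lat[sig_genes[j], ] +
        stats::rnorm(n_cells, 0, sigma_prop / sqrt(w_norm))
    }

    datasets[[ds]] <- list(
      counts = counts,
      cells = data.frame(cell_id = cell_ids, dataset = ds_id,
                         subclass = subclass, quality_true = qual,
                         stringsAsFactors = FALSE),
      props = data.frame(cell_id = cell_ids, props, check.names = FALSE,
                         stringsAsFactors = FALSE),
      protocol = protocols[ds])
    truth_cells[[ds]] <- data.frame(cell_id = cell_ids, dataset = ds_id,
                                    quality_true = qual,
                                    stringsAsFactors = FALSE)
  }
  names(datasets) <- sprintf("ds%d", seq_len(n_datasets))
  list(datasets = datasets, protein_coding = protein_coding,
       on_markers = on_markers, off_markers = off_markers,
       truth = list(beta = stats::setNames(rep(beta, n_signal), sig_genes),
                    cells = do.call(rbind, truth_cells)),
       pairs = data.frame(gene = sig_genes, property = prop_names,
                          stringsAsFactors = FALSE),
       seed = seed)
}

#' Simulate a reference atlas of cluster centroids
#'
#' Clusters carry a shared subclass signal plus a smaller cluster-specific
#' signal, so nearest-centroid mapping can be scored at the subclass level.
#'
#' @param n_genes gene universe size
#' @param n_clusters number of clusters
#' @param n_subclasses number of subclasses (clusters assigned round-robin)
#' @param subclass_sd,cluster_sd signal sds (log2 units)
#' @param n_hvgs number of HVGs declared by the atlas
#' @param seed RNG seed
#' @return atlas list (\code{centroids}, \code{cluster_subclass},
#'   \code{hvgs}) as consumed by [map_cells_to_atlas()]
#' @export
simulate_reference_atlas <- function(n_genes = 500, n_clusters = 10,
                                     n_subclasses = 5, subclass_sd = 1.5,
                                     cluster_sd = 0.5, n_hvgs = 300,
                                     seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  clusters <- sprintf("cl%02d", seq_len(n_clusters))
  subclasses <- sprintf("sub%d", rep_len(seq_len(n_subclasses), n_clusters))
  base <- stats::runif(n_genes, 0, 6)
  cent <- matrix(NA_real_, n_genes, n_clusters,
                 dimnames = list(genes, clusters))
  sub_sig <- matrix(stats::rnorm(n_genes * n_subclasses, 0, subclass_sd),
                    n_genes, n_subclasses)
  for (k in seq_len(n_clusters)) {
    cent[, k] <- pmax(0, base + sub_sig[, rep_len(seq_len(n_subclasses),
                                                  n_clusters)[k]] +
                        stats::rnorm(n_genes, 0, cluster_sd))
  }
  v <- apply(cent, 1, stats::var)
  hvgs <- genes[order(-v)][seq_len(min(n_hvgs, n_genes))]
  list(centroids = cent,
       cluster_subclass = stats::setNames(subclasses, clusters),
       hvgs = hvgs)
}

#' Draw query cells from atlas clusters at a given noise level
#'
#' Cells are centroids plus Gaussian noise whose sd is \code{noise_frac}
#' times the signal sd (the sd of gene-centered centroid values).
#'
#' @param atlas output of [simulate_reference_atlas()]
#' @param n_per_cluster cells per cluster
#' @param noise_frac noise sd as a fraction of the signal sd
#' @param seed RNG seed
#' @return list with \code{expr} (genes x cells), \code{truth} (data frame
#'   \code{cell_id}, \code{cluster}, \code{subclass})
#' @export
simulate_atlas_query_cells <- function(atlas, n_per_cluster = 20,
                                       noise_frac = 0.2, seed = 1) {
  set.seed(seed)
  cent <- atlas$centroids
  sig_sd <- stats::sd(cent - rowMeans(cent))
  clusters <- colnames(cent)
  n_cells <- length(clusters) * n_per_cluster
  cell_ids <- sprintf("q%04d", seq_len(n_cells))
  true_cl <- rep(clusters, each = n_per_cluster)
  expr <- cent[, true_cl, drop = FALSE] +
    matrix(stats::rnorm(nrow(cent) * n_cells, 0, noise_frac * sig_sd),
           nrow(cent), n_cells)
  expr[expr < 0] <- 0
  colnames(expr) <- cell_ids
  list(expr = expr,
       truth = data.frame(cell_id = cell_ids, cluster = true_cl,
                          subclass = unname(atlas$cluster_subclass[true_cl]),
                          stringsAsFactors = FALSE))
}
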