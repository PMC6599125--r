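# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: OLS by explicit normal equations, BH by literal
# rank arithmetic, Spearman by rank-then-Pearson.

oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  coef <- solve(XtX, t(X) %*% y)[, 1]
  res <- y - X %*% coef
  rss <- sum(res^2)
  df <- nrow(X) - ncol(X)
  sigma2 <- rss / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- coef / se
  list(coef = coef, se = se, p = 2 * stats::pt(-abs(tval), df),
       rss = rss, df = df)
}

oracle_f_test <- function(rss_r, rss_f, df_num, df_den) {
  Fs <- ((rss_r - rss_f) / df_num) / (rss_f / df_den)
  list(F = Fs, p = stats::pf(Fs, df_num, df_den, lower.tail = FALSE))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  # cumulative minimum from the largest p downward
  for (i in (m - 1):1) if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

oracle_spearman <- function(a, b) stats::cor(rank(a), rank(b))

# small deterministic two-class panel: expression rows are genes, one
# synthetic property per gene named p_<gene>
make_tiny_panel <- function(n_exc = 5, n_inh = 7, n_genes = 4, seed = 99) {
  set.seed(seed)
  n <- n_exc + n_inh
  types <- sprintf("t%02d", seq_len(n))
  cls <- stats::setNames(c(rep("excitatory", n_exc), rep("inhibitory", n_inh)),
                         types)
  genes <- sprintf("g%02d", seq_len(n_genes))
  expr <- matrix(stats::rnorm(n_genes * n, 5, 1), n_genes, n,
                 dimnames = list(genes, types))
  props <- matrix(stats::rnorm(n * n_genes), n, n_genes,
                  dimnames = list(types, paste0("p_", genes)))
  ct_panel(expr, props, cls,
           pairs = data.frame(gene = genes, property = paste0("p_", genes),
                              stringsAsFactors = FALSE))
}

# assemble mixed-model input from a simulate_patchseq() bundle for one
# signal gene, using true subclasses and computed quality scores
patchseq_mixed_input <- function(ps, gene_index = 1) {
  norm <- lapply(ps$datasets, function(d)
    normalize_patchseq(d$counts, d$protocol, ps$protein_coding))
  expr_all <- do.call(cbind, norm)
  g <- ps$pairs$gene[gene_index]
  pr <- ps$pairs$property[gene_index]
  do.call(rbind, lapply(names(ps$datasets), function(nm) {
    d <- ps$datasets[[nm]]
    w <- compute_quality_score(norm[[nm]], ps$on_markers, ps$off_markers)
    data.frame(expr = unname(expr_all[g, d$cells$cell_id]),
               prop = d$props[[pr]],
               dataset = d$cells$dataset, subclass = d$cells$subclass,
               w = unname(w[d$cells$cell_id]), stringsAsFactors = FALSE)
  }))
}
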