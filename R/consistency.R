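#' Gene-property slopes from a single-class reference panel
#'
#' Fits the class-independent model per gene on a panel containing a single
#' cell class (the role played by literature-pooled reference data restricted
#' to non-projecting types).  Errors if the panel mixes classes.
#'
#' @param panel single-class [ct_panel()] with at least 3 types
#' @param pairs data frame \code{(gene, property)}; defaults to
#'   \code{panel$pairs}
#' @return named numeric vector of slopes, one per gene
#' @export
single_class_slopes <- function(panel, pairs = NULL) {
  stopifnot(inherits(panel, "ct_panel"))
  if (length(unique(panel$class)) != 1)
    stop("panel contains more than one cell class; single_class_slopes requires one")
  if (ncol(panel$expr) < 3) stop("at least 3 types required")
  if (is.null(pairs)) pairs <- panel$pairs
  if (is.null(pairs)) stop("`pairs` required when the panel carries no pairing")
  slopes <- vapply(seq_len(nrow(pairs)), function(i) {
    G <- panel$expr[pairs$gene[i], ]
    P <- panel$props[, pairs$property[i]]
    ok <- !is.na(G) & !is.na(P)
    if (sum(ok) < 3 || stats::sd(G[ok]) == 0) return(NA_real_)
    f <- fit_ols(cbind(intercept = rep(1, sum(ok)), G = G[ok]), P[ok])
    f$coef[["G"]]
  }, numeric(1))
  stats::setNames(slopes, pairs$gene)
}

#' Slopes per gene from a (possibly two-class) panel under a chosen model
#'
#' \code{"independent"} returns the marginal slope, \code{"conditional"} the
#' class-adjusted slope from P ~ G + C.
#'
#' @param panel a [ct_panel()]
#' @param pairs data frame \code{(gene, property)}
#' @param model \code{"independent"} or \code{"conditional"}
#' @return named numeric vector of slopes
#' @export
panel_slopes <- function(panel, pairs = NULL,
                         model = c("independent", "conditional")) {
  model <- match.arg(model)
  if (is.null(pairs)) pairs <- panel$pairs
  slopes <- vapply(seq_len(nrow(pairs)), function(i) {
    G <- panel$expr[pairs$gene[i], ]
    P <- panel$props[, pairs$property[i]]
    ok <- !is.na(G) & !is.na(P)
    G <- G[ok]; P <- P[ok]
    C <- as.numeric(panel$class[ok] == "inhibitory")
    if (length(G) < 4 || stats::sd(G) == 0) return(NA_real_)
    one <- rep(1, length(G))
    d <- if (model == "independent") cbind(intercept = one, G = G)
         else cbind(intercept = one, G = G, C = C)
    f <- fit_ols(d, P)
    f$coef[["G"]]
  }, numeric(1))
  stats::setNames(slopes, pairs$gene)
}

align_slopes <- function(a, b) {
  common <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  list(a = a[common], b = b[common], genes = common)
}

#' Spearman correlation between two per-gene slope vectors
#'
#' Aligned on the intersection of genes present (non-missing) in both
#' vectors; average ranks for ties.
#'
#' @param slopes_a,slopes_b named numeric vectors
#' @return Spearman rho
#' @export
consistency_spearman <- function(slopes_a, slopes_b) {
  al <- align_slopes(slopes_a, slopes_b)
  if (length(al$genes) < 10)
    stop("fewer than 10 genes shared between slope vectors (",
         length(al$genes), "); correlation uninterpretable")
  stats::cor(al$a, al$b, method = "spearman")
}

#' Bootstrap confidence interval for slope consistency
#'
#' Resamples gene pairs with replacement \code{n_boot} times, recomputing
#' the Spearman correlation each time; the CI is the 2.5th / 97.5th
#' percentile of the resampled correlations.  Seeded and reproducible.
#'
#' @param slopes_a,slopes_b named numeric slope vectors
#' @param n_boot number of resamples
#' @param seed RNG seed
#' @return list of class \code{consistency_result}: \code{rho},
#'   \code{ci_low}, \code{ci_high}, \code{rhos} (resampled values),
#'   \code{n_genes}, \code{n_boot}, \code{seed}
#' @export
bootstrap_consistency <- function(slopes_a, slopes_b, n_boot = 100, seed = 1) {
  al <- align_slopes(slopes_a, slopes_b)
  n <- length(al$genes)
  if (n < 10) stop("fewer than 10 paired genes")
  rho <- stats::cor(al$a, al$b, method = "spearman")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  rhos <- vapply(seq_len(n_boot), function(b) {
    i <- idx[, b]
    suppressWarnings(stats::cor(al$a[i], al$b[i], method = "spearman"))
  }, numeric(1))
  ci <- stats::quantile(rhos, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(rho = rho, ci_low = ci[1], ci_high = ci[2], rhos = rhos,
                 n_genes = n, n_boot = n_boot, seed = seed),
            class = "consistency_result")
}

#' Paired bootstrap comparison of model consistency
#'
#' Compares the cross-dataset slope consistency of two models (typically
#' class-independent vs class-conditional) with a paired bootstrap: within
#' each iteration the same gene resample is used for both models, the
#' difference of the two resampled correlations is recorded, and the
#' comparison is significant when the 95% percentile interval of the
#' differences excludes zero.
#'
#' @param a_model1,b_model1 paired slope vectors for the first model
#' @param a_model2,b_model2 paired slope vectors for the second model
#' @param n_boot number of resamples
#' @param seed RNG seed
#' @return list of class \code{model_comparison}: per-model rho and CI,
#'   \code{delta} (mean difference model2 - model1), \code{ci_low},
#'   \code{ci_high}, \code{significant}
#' @export
compare_model_consistency <- function(a_model1, b_model1, a_model2, b_model2,
                                      n_boot = 100, seed = 1) {
  al1 <- align_slopes(a_model1, b_model1)
  al2 <- align_slopes(a_model2, b_model2)
  if (!identical(al1$genes, al2$genes))
    stop("gene sets differ between the two models; a paired comparison requires identical genes")
  n <- length(al1$genes)
  if (n < 10) stop("fewer than 10 paired genes")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  boot_rho <- function(al) vapply(seq_len(n_boot), function(b) {
    i <- idx[, b]
    suppressWarnings(stats::cor(al$a[i], al$b[i], method = "spearman"))
  }, numeric(1))
  r1 <- boot_rho(al1)
  r2 <- boot_rho(al2)
  d <- r2 - r1
  ci <- stats::quantile(d, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(rho_model1 = stats::cor(al1$a, al1$b, method = "spearman"),
                 rho_model2 = stats::cor(al2$a, al2$b, method = "spearman"),
                 rhos_model1 = r1, rhos_model2 = r2,
                 delta = mean(d), ci_low = ci[1], ci_high = ci[2],
                 significant = ci[1] > 0 || ci[2] < 0,
                 n_genes = n, n_boot = n_boot, seed = seed),
            class = "model_comparison")
}
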