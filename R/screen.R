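#' Benjamini-Hochberg q-values
#'
#' Computes q = p * (m / i) where i is the significance rank (most significant
#' = 1), followed by a cumulative minimum taken from the largest p-value
#' downward, restoring the original order.  Tied p-values share a q.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return q-values in the input order
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) stop("empty p-value family")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)        # start from the highest p
  rank_i <- m - seq_along(p) + 1L         # significance rank of each sorted entry
  q_sorted <- cummin(pmin(1, p[o] * m / rank_i))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Design matrices for the four type-level models; class coded
# excitatory = 0 (reference), inhibitory = 1.
design_mats <- function(G, C) {
  one <- rep(1, length(G))
  list(m1 = cbind(intercept = one, G = G),
       m2 = cbind(intercept = one, C = C),
       m3 = cbind(intercept = one, G = G, C = C),
       m4 = cbind(intercept = one, G = G, C = C, GxC = G * C))
}

#' Fit the model family for one gene x property pair
#'
#' Fits, on the cell-type profiles, the class-independent model (P ~ G), the
#' class-only model (P ~ C), the class-conditional model (P ~ G + C), the
#' interaction model (P ~ G + C + G:C) and the class-independent model
#' restricted to inhibitory types.  The class-conditional p-value comes from
#' the nested ANOVA of model 2 vs model 3, the interaction p-value from
#' model 3 vs model 4.  Betas are per log2 unit, i.e. per 2-fold change in
#' expression.  Class-aware models are only fitted when the gene is expressed
#' in both classes (nonzero mean log expression in at least one type of each)
#' and each class contributes at least \code{min_types_per_class} types; a
#' skipped fit is recorded with \code{tested = FALSE}, distinct from
#' non-significance.
#'
#' @param panel a [ct_panel()]
#' @param gene,property ids present in the panel
#' @param min_types_per_class minimum types per class for class-aware models
#' @return data frame with one row per model
#' @export
fit_gene_property <- function(panel, gene, property, min_types_per_class = 2) {
  stopifnot(inherits(panel, "ct_panel"))
  G_all <- panel$expr[gene, ]
  P_all <- panel$props[, property]
  ok <- !is.na(G_all) & !is.na(P_all)
  G <- G_all[ok]; P <- P_all[ok]
  C <- as.numeric(panel$class[ok] == "inhibitory")
  n <- length(G)

  row <- function(model, beta = NA_real_, se = NA_real_, p = NA_real_,
                  F = NA_real_, df_num = NA_real_, df_den = NA_real_,
                  slope_exc = NA_real_, slope_inh = NA_real_, n_types = n,
                  tested = TRUE, delta_expr = NA_real_) {
    data.frame(gene = gene, property = property, model = model,
               beta = beta, se = se, p = p, F = F,
               df_num = df_num, df_den = df_den,
               slope_exc = slope_exc, slope_inh = slope_inh,
               delta_expr = delta_expr, n_types = n_types, tested = tested,
               stringsAsFactors = FALSE)
  }

  out <- vector("list", 5)
  # class-independent model on all types
  if (n >= 3 && stats::sd(G) > 0) {
    f1 <- fit_ols(cbind(intercept = rep(1, n), G = G), P)
    out[[1]] <- row("independent", beta = f1$coef[["G"]], se = f1$se[["G"]],
                    p = f1$p[["G"]])
  } else {
    out[[1]] <- row("independent", tested = FALSE)
  }

  has_both <- all(c(0, 1) %in% C)
  delta_expr <- if (has_both) mean(G[C == 1]) - mean(G[C == 0]) else NA_real_
  expressed_both <- has_both && any(G[C == 0] > 0) && any(G[C == 1] > 0)
  enough <- has_both && sum(C == 0) >= min_types_per_class &&
    sum(C == 1) >= min_types_per_class
  class_ok <- expressed_both && enough && stats::sd(G) > 0

  if (class_ok) {
    d <- design_mats(G, C)
    f2 <- fit_ols(d$m2, P)
    f3 <- fit_ols(d$m3, P)
    a23 <- anova_nested(f2, f3)
    out[[2]] <- row("class_only", beta = f2$coef[["C"]], se = f2$se[["C"]],
                    p = f2$p[["C"]], delta_expr = delta_expr)
    out[[3]] <- row("conditional", beta = f3$coef[["G"]], se = f3$se[["G"]],
                    p = a23$p, F = a23$F, df_num = a23$df_num,
                    df_den = a23$df_den, delta_expr = delta_expr)
    int_ok <- stats::sd(G[C == 0]) > 0 && stats::sd(G[C == 1]) > 0
    if (int_ok) {
      f4 <- fit_ols(d$m4, P)
      a34 <- anova_nested(f3, f4)
      sl <- within_class_slopes(f4)
      out[[4]] <- row("interaction", beta = f4$coef[["GxC"]], se = f4$se[["GxC"]],
                      p = a34$p, F = a34$F, df_num = a34$df_num,
                      df_den = a34$df_den, slope_exc = sl[["slope_exc"]],
                      slope_inh = sl[["slope_inh"]], delta_expr = delta_expr)
    } else {
      out[[4]] <- row("interaction", tested = FALSE, delta_expr = delta_expr)
    }
  } else {
    out[[2]] <- row("class_only", tested = FALSE, delta_expr = delta_expr)
    out[[3]] <- row("conditional", tested = FALSE, delta_expr = delta_expr)
    out[[4]] <- row("interaction", tested = FALSE, delta_expr = delta_expr)
  }

  inh <- C == 1
  if (sum(inh) >= 3 && stats::sd(G[inh]) > 0) {
    fi <- fit_ols(cbind(intercept = rep(1, sum(inh)), G = G[inh]), P[inh])
    out[[5]] <- row("inhibitory_only", beta = fi$coef[["G"]], se = fi$se[["G"]],
                    p = fi$p[["G"]], n_types = sum(inh))
  } else {
    out[[5]] <- row("inhibitory_only", tested = FALSE, n_types = sum(inh))
  }
  do.call(rbind, out)
}

#' Per-class slopes from an interaction-model fit
#'
#' With class coded excitatory = 0 / inhibitory = 1, the excitatory slope is
#' the gene coefficient and the inhibitory slope is the gene coefficient plus
#' the interaction coefficient; these equal the slopes of separate per-class
#' simple regressions.
#'
#' @param fit a [fit_ols()] result for the interaction design
#'   (intercept, G, C, GxC)
#' @return named vector \code{c(slope_exc, slope_inh)}
#' @export
within_class_slopes <- function(fit) {
  if (!all(c("G", "GxC") %in% fit$terms))
    stop("fit is not an interaction-model fit")
  c(slope_exc = unname(fit$coef[["G"]]),
    slope_inh = unname(fit$coef[["G"]] + fit$coef[["GxC"]]))
}

#' Test for a class effect on a property
#'
#' The class-only model (P ~ C) fitted across types; the F statistic equals
#' the squared pooled-variance two-sample t statistic.
#'
#' @param panel a [ct_panel()]
#' @param property property id
#' @return list with \code{F}, \code{p}, \code{mean_exc}, \code{mean_inh},
#'   \code{n_exc}, \code{n_inh}
#' @export
class_effect_test <- function(panel, property) {
  P <- panel$props[, property]
  ok <- !is.na(P)
  P <- P[ok]
  C <- as.numeric(panel$class[ok] == "inhibitory")
  if (length(unique(C)) < 2) stop("both classes required for a class-effect test")
  if (sum(C == 0) < 2 || sum(C == 1) < 2)
    stop("at least 2 types per class required")
  one <- rep(1, length(P))
  f0 <- fit_ols(cbind(intercept = one), P)
  f2 <- fit_ols(cbind(intercept = one, C = C), P)
  a <- anova_nested(f0, f2)
  list(F = a$F, p = a$p, mean_exc = mean(P[C == 0]), mean_inh = mean(P[C == 1]),
       n_exc = sum(C == 0), n_inh = sum(C == 1))
}

#' Classify a gene-property relationship from its q-values
#'
#' At the primary FDR threshold: significant in the class-independent model
#' only = class-driven; significant in the class-conditional model only =
#' non-class-driven relationship obscured by class; significant in both =
#' shared.  A significant interaction is layered on top: it upgrades an
#' otherwise-null pair to \code{interaction_only} and a conditional hit to
#' \code{conditional_and_interaction}.  Vectorized.
#'
#' @param q_independent,q_conditional,q_interaction q-value vectors
#'   (\code{q_interaction} may be NA where the interaction was not tested)
#' @param fdr primary significance threshold
#' @return data frame with \code{category} and logical
#'   \code{interaction_significant}
#' @export
classify_relationship <- function(q_independent, q_conditional,
                                  q_interaction = NA_real_, fdr = 0.1) {
  n <- max(length(q_independent), length(q_conditional))
  q_ind <- rep_len(q_independent, n)
  q_cond <- rep_len(q_conditional, n)
  q_int <- rep_len(q_interaction, n)
  if (anyNA(q_ind) || anyNA(q_cond))
    stop("q_independent and q_conditional must be non-missing")
  sig_i <- q_ind <= fdr
  sig_c <- q_cond <= fdr
  sig_x <- !is.na(q_int) & q_int <= fdr
  category <- rep("none", n)
  category[sig_i & !sig_c] <- "class_driven"
  category[!sig_i & sig_c] <- "non_class_driven_obscured"
  category[sig_i & sig_c] <- "non_class_driven_shared"
  category[sig_x & category == "none"] <- "interaction_only"
  category[sig_x & sig_c] <- "conditional_and_interaction"
  data.frame(category = category, interaction_significant = sig_x,
             stringsAsFactors = FALSE)
}

#' Run the gene-property screen over a profile panel
#'
#' Fits the model family for every requested gene x property pair, applies
#' BH-FDR within each family, and classifies every pair.  The FDR family is
#' one property x one model by default (\code{fdr_family = "property"});
#' \code{"model"} pools all pairs per model, which is the appropriate family
#' for synthetic panels where each gene drives its own property column.
#' Not-tested fits are excluded from the family size m.
#'
#' @param panel a [ct_panel()]
#' @param pairs data frame \code{(gene, property)}; defaults to
#'   \code{panel$pairs}, else the full gene x property cross
#' @param fdr primary FDR threshold for classification
#' @param fdr_family \code{"property"} or \code{"model"}
#' @param thresholds FDR levels for the per-property significant-gene counts
#' @return list of class \code{nc_screen} with elements \code{fits} (long
#'   table with q), \code{calls} (one row per pair), \code{counts}
#'   (significant genes per property x model x threshold) and \code{overlap}
#'   (independent/conditional overlap per property)
#' @export
screen <- function(panel, pairs = NULL, fdr = 0.1,
                   fdr_family = c("property", "model"),
                   thresholds = c(0.1, 0.05, 0.01, 0.001)) {
  stopifnot(inherits(panel, "ct_panel"))
  fdr_family <- match.arg(fdr_family)
  if (is.null(pairs)) pairs <- panel$pairs
  if (is.null(pairs))
    pairs <- expand.grid(gene = rownames(panel$expr),
                         property = colnames(panel$props),
                         stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) stop("empty gene/property pair list")

  fits <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs)))
    fits[[i]] <- fit_gene_property(panel, pairs$gene[i], pairs$property[i])
  fits <- do.call(rbind, fits)

  fam <- if (fdr_family == "property") paste(fits$property, fits$model)
         else fits$model
  fits$q <- NA_real_
  tested <- fits$tested & !is.na(fits$p)
  for (f in unique(fam[tested])) {
    idx <- which(tested & fam == f)
    fits$q[idx] <- bh_fdr(fits$p[idx])
  }

  wide <- function(model, col) {
    sub <- fits[fits$model == model, ]
    sub[[col]][match(paste(pairs$gene, pairs$property),
                     paste(sub$gene, sub$property))]
  }
  q_ind <- wide("independent", "q")
  q_cond <- wide("conditional", "q")
  q_int <- wide("interaction", "q")
  testable <- !is.na(q_ind) & !is.na(q_cond)
  calls <- data.frame(pairs, q_independent = q_ind, q_conditional = q_cond,
                      q_interaction = q_int,
                      category = NA_character_,
                      interaction_significant = NA,
                      stringsAsFactors = FALSE)
  if (any(testable)) {
    cl <- classify_relationship(q_ind[testable], q_cond[testable],
                                q_int[testable], fdr = fdr)
    calls$category[testable] <- cl$category
    calls$interaction_significant[testable] <- cl$interaction_significant
  }

  ok_fit <- fits$tested & !is.na(fits$q)
  sub_fits <- fits[ok_fit, , drop = FALSE]
  counts <- do.call(rbind, lapply(split(sub_fits,
                                        list(sub_fits$property, sub_fits$model),
                                        drop = TRUE),
                                  function(sub) {
    cnt <- vapply(thresholds, function(th) sum(sub$q <= th), numeric(1))
    data.frame(property = sub$property[1], model = sub$model[1],
               t(stats::setNames(cnt, paste0("n_q", thresholds))),
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL

  overlap <- do.call(rbind, lapply(split(calls[testable, , drop = FALSE],
                                         calls$property[testable]),
                                   function(sub) {
    data.frame(property = sub$property[1],
               n_independent = sum(sub$q_independent <= fdr),
               n_conditional = sum(sub$q_conditional <= fdr),
               n_both = sum(sub$q_independent <= fdr & sub$q_conditional <= fdr),
               stringsAsFactors = FALSE)
  }))
  rownames(overlap) <- NULL

  structure(list(fits = fits, calls = calls, counts = counts,
                 overlap = overlap, fdr = fdr, fdr_family = fdr_family),
            class = "nc_screen")
}

#' Select exemplar genes for a property
#'
#' Picks up to \code{k} genes with the smallest class-conditional q among
#' those significant conditionally (q <= \code{fdr_primary}) but
#' non-significant (q > \code{fdr_exclusion}) in both the class-independent
#' and interaction models.  Ties in q are broken by larger |beta|, then
#' lexicographic gene id.
#'
#' @param scr an \code{nc_screen} result
#' @param property property id
#' @param k maximum number of genes
#' @param fdr_primary,fdr_exclusion thresholds
#' @return character vector of gene ids (possibly shorter than k)
#' @export
select_top_genes <- function(scr, property, k = 3, fdr_primary = 0.1,
                             fdr_exclusion = 0.2) {
  calls <- scr$calls[scr$calls$property == property, , drop = FALSE]
  cond <- scr$fits[scr$fits$model == "conditional" &
                     scr$fits$property == property, ]
  beta <- cond$beta[match(calls$gene, cond$gene)]
  ok <- !is.na(calls$q_conditional) & calls$q_conditional <= fdr_primary &
    !is.na(calls$q_independent) & calls$q_independent > fdr_exclusion &
    !is.na(calls$q_interaction) & calls$q_interaction > fdr_exclusion
  calls <- calls[ok, , drop = FALSE]
  beta <- beta[ok]
  if (nrow(calls) == 0) return(character(0))
  o <- order(calls$q_conditional, -abs(beta), calls$gene)
  utils::head(calls$gene[o], k)
}
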