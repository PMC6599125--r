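#' Principal components of a property family across cell types
#'
#' Standardizes each property of the chosen family (ephys or morph) to mean 0
#' / sd 1 across cell types, then decomposes with PCA.  Types with any
#' missing property in the family are dropped (with a logged list) rather
#' than imputed.  Four components are computed; the first
#' \code{n_use} (default 3) are exposed as derived properties.  Component
#' signs are fixed by requiring the largest-magnitude loading of each
#' component to be positive.
#'
#' @param panel a [ct_panel()]
#' @param family \code{"ephys"} or \code{"morph"}
#' @param n_comp number of components to compute
#' @param n_use number of components exposed as derived properties
#' @return list of class \code{pc_result}: \code{scores} (types x components),
#'   \code{loadings} (properties x components, orthonormal columns),
#'   \code{variance_explained} (fractions over all property-space variance),
#'   \code{center}, \code{scale}, \code{types_used}
#' @export
fit_property_pca <- function(panel, family = c("ephys", "morph"),
                             n_comp = 4, n_use = 3) {
  stopifnot(inherits(panel, "ct_panel"))
  family <- match.arg(family)
  props <- panel$prop_meta$property[panel$prop_meta$family == family]
  props <- intersect(props, colnames(panel$props))
  if (length(props) < 2) stop("need at least 2 properties in family '", family, "'")
  X <- panel$props[, props, drop = FALSE]
  complete <- stats::complete.cases(X)
  if (any(!complete))
    nc_log("fit_property_pca: dropping incomplete types: ",
           paste(rownames(X)[!complete], collapse = ", "))
  X <- X[complete, , drop = FALSE]
  n_comp <- min(n_comp, ncol(X), nrow(X) - 1)
  if (nrow(X) < max(5, n_comp + 1))
    stop("fewer complete cell types (", nrow(X), ") than required")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  rot <- pc$rotation[, seq_len(n_comp), drop = FALSE]
  scores <- pc$x[, seq_len(n_comp), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(rot))) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  prefix <- if (family == "ephys") "E_PC" else "M_PC"
  colnames(rot) <- colnames(scores) <- paste0(prefix, seq_len(n_comp))
  structure(list(scores = scores[, seq_len(min(n_use, n_comp)), drop = FALSE],
                 scores_all = scores,
                 loadings = rot,
                 variance_explained = ve[seq_len(n_comp)],
                 variance_explained_all = ve,
                 center = pc$center, scale = pc$scale,
                 types_used = rownames(X), family = family),
            class = "pc_result")
}

#' Join PC scores onto a panel as derived properties
#'
#' @param panel a [ct_panel()]
#' @param pc a \code{pc_result}
#' @return a new panel whose property table gains the PC columns (NA for
#'   types excluded from the PCA)
#' @export
add_pc_properties <- function(panel, pc) {
  new_props <- matrix(NA_real_, nrow(panel$props), ncol(pc$scores),
                      dimnames = list(rownames(panel$props), colnames(pc$scores)))
  new_props[pc$types_used, ] <- pc$scores
  props <- cbind(panel$props, new_props)
  meta <- rbind(panel$prop_meta,
                data.frame(property = colnames(pc$scores),
                           family = paste0(pc$family, "_pc"),
                           stringsAsFactors = FALSE))
  ct_panel(panel$expr, props, panel$class, prop_meta = meta,
           pairs = panel$pairs)
}

#' Overlap between raw-property and PC screen hits
#'
#' For each raw property with at least one significant gene, the percentage
#' of its significant genes (at \code{fdr}) that are also significant for
#' each PC, in the same model.  Optionally also reports Spearman correlations
#' between each PC score and each raw property across the types used in the
#' PCA.
#'
#' @param scr_props screen result over raw properties
#' @param scr_pcs screen result over PC-derived properties
#' @param model which model's q-values to compare
#' @param fdr significance threshold
#' @param panel optional panel carrying both raw properties and PC columns,
#'   for the score-property correlations
#' @return list with \code{overlap} (property x pc, percent) and optionally
#'   \code{spearman}
#' @export
pc_property_overlap <- function(scr_props, scr_pcs, model = "conditional",
                                fdr = 0.1, panel = NULL) {
  sig_set <- function(scr) {
    f <- scr$fits[scr$fits$model == model & !is.na(scr$fits$q) &
                    scr$fits$q <= fdr, ]
    split(f$gene, f$property)
  }
  sp <- sig_set(scr_props)
  sc <- sig_set(scr_pcs)
  sp <- sp[vapply(sp, length, integer(1)) > 0]
  pcs <- unique(scr_pcs$fits$property)
  overlap <- do.call(rbind, lapply(names(sp), function(prop) {
    pct <- vapply(pcs, function(pc) {
      g <- sc[[pc]]
      100 * length(intersect(sp[[prop]], g)) / length(sp[[prop]])
    }, numeric(1))
    data.frame(property = prop, pc = pcs, percent_overlap = unname(pct),
               n_significant = length(sp[[prop]]), stringsAsFactors = FALSE)
  }))
  out <- list(overlap = overlap)
  if (!is.null(panel)) {
    raw <- names(sp)
    cors <- do.call(rbind, lapply(raw, function(prop) {
      rho <- vapply(pcs, function(pc) {
        suppressWarnings(stats::cor(panel$props[, prop], panel$props[, pc],
                                    method = "spearman",
                                    use = "pairwise.complete.obs"))
      }, numeric(1))
      data.frame(property = prop, pc = pcs, spearman = unname(rho),
                 stringsAsFactors = FALSE)
    }))
    out$spearman <- cors
  }
  out
}
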