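#' Ordinary least squares with explicit design matrix
#'
#' QR-based least squares returning coefficients, standard errors, t-based
#' p-values, residual sum of squares and residual degrees of freedom.  A
#' rank-deficient design is an error naming the collinear columns.  When the
#' fit is exact (RSS numerically zero) coefficient p-values degenerate: 0 for
#' a nonzero coefficient, 1 otherwise.
#'
#' @param design numeric matrix including any intercept column, with column
#'   names
#' @param response numeric vector
#' @return list with \code{coef}, \code{se}, \code{t}, \code{p}, \code{rss},
#'   \code{df}, \code{n}, \code{terms} (design column names)
#' @export
fit_ols <- function(design, response) {
  if (!is.matrix(design)) design <- as.matrix(design)
  n <- nrow(design); k <- ncol(design)
  if (length(response) != n) stop("design/response length mismatch")
  if (n <= k) stop("need more observations (", n, ") than coefficients (", k, ")")
  if (is.null(colnames(design))) colnames(design) <- paste0("x", seq_len(k))
  dqr <- qr(design)
  if (dqr$rank < k) {
    bad <- colnames(design)[dqr$pivot[seq(dqr$rank + 1L, k)]]
    stop("singular fit: collinear columns: ", paste(bad, collapse = ", "))
  }
  coef <- qr.coef(dqr, response)
  res <- as.numeric(response - design %*% coef)
  rss <- sum(res^2)
  df <- n - k
  scale_ref <- sum(response^2) + 1
  if (rss < 1e-12 * scale_ref) {
    # exact fit: t statistics are degenerate
    se <- rep(0, k)
    p <- ifelse(abs(coef) > 1e-10, 0, 1)
    tval <- ifelse(abs(coef) > 1e-10, Inf, 0)
  } else {
    sigma2 <- rss / df
    R <- qr.R(dqr)[, order(dqr$pivot), drop = FALSE]
    xtx_inv <- chol2inv(chol(crossprod(R[, , drop = FALSE])))
    # crossprod(R) = X'X up to the (identity) pivot for full-rank designs
    se <- sqrt(diag(xtx_inv) * sigma2)
    tval <- coef / se
    p <- 2 * stats::pt(-abs(tval), df)
  }
  names(se) <- names(p) <- names(coef)
  list(coef = coef, se = se, t = tval, p = p, rss = rss, df = df, n = n,
       terms = colnames(design))
}

#' F-test between nested least-squares fits
#'
#' @param reduced,full [fit_ols()] results on the same response; the reduced
#'   model's terms must be a subset of the full model's
#' @return list with \code{F}, \code{p}, \code{df_num}, \code{df_den}.  An
#'   exactly-fitting full model gives p = 0 when it improves on the reduced
#'   model and p = 1 when both fit exactly.
#' @export
anova_nested <- function(reduced, full) {
  if (!all(reduced$terms %in% full$terms))
    stop("models are not nested: reduced terms ",
         paste(setdiff(reduced$terms, full$terms), collapse = ", "),
         " absent from full model")
  if (reduced$n != full$n) stop("models fitted on different numbers of observations")
  df_num <- reduced$df - full$df
  if (df_num <= 0) stop("full model adds no parameters")
  df_den <- full$df
  tol <- 1e-12 * (reduced$rss + 1)
  if (full$rss < tol) {
    improves <- (reduced$rss - full$rss) > tol
    return(list(F = if (improves) Inf else 0,
                p = if (improves) 0 else 1,
                df_num = df_num, df_den = df_den))
  }
  Fstat <- max(0, (reduced$rss - full$rss) / df_num) / (full$rss / df_den)
  p <- stats::pf(Fstat, df_num, df_den, lower.tail = FALSE)
  list(F = Fstat, p = p, df_num = df_num, df_den = df_den)
}
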