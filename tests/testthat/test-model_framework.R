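test_that("fit_ols matches the normal-equations oracle and flags collinearity", {
  # exact fit: P = 2 G + 1
  G <- c(1, 2, 3, 4)
  f <- fit_ols(cbind(intercept = 1, G = G), 2 * G + 1)
  expect_equal(unname(f$coef), c(1, 2), tolerance = 1e-12)
  expect_equal(f$rss, 0, tolerance = 1e-12)

  expect_error(fit_ols(cbind(intercept = rep(1, 5), G = rep(3, 5)), rnorm(5)),
               "singular.*G")

  set.seed(10)
  for (i in 1:50) {
    n <- sample(10:48, 1)
    X <- cbind(intercept = 1, a = rnorm(n), b = rnorm(n))
    y <- rnorm(n)
    f <- fit_ols(X, y)
    o <- oracle_ols(X, y)
    expect_equal(f$coef, o$coef, tolerance = 1e-8)
    expect_equal(f$se, o$se, tolerance = 1e-8)
    expect_equal(f$p, o$p, tolerance = 1e-8)
    expect_equal(f$rss, o$rss, tolerance = 1e-8)
  }
})

test_that("nested ANOVA: F = t^2 for one added predictor, degenerate cases handled", {
  set.seed(11)
  for (i in 1:20) {
    n <- 30
    X1 <- cbind(intercept = rep(1, n))
    X2 <- cbind(intercept = 1, g = rnorm(n))
    y <- rnorm(n)
    f1 <- fit_ols(X1, y); f2 <- fit_ols(X2, y)
    a <- anova_nested(f1, f2)
    expect_equal(a$F, unname(f2$t[["g"]]^2), tolerance = 1e-10)
    expect_equal(a$p, unname(f2$p[["g"]]), tolerance = 1e-10)
  }
  # identical RSS (predictor orthogonal to the response) -> F = 0, p = 1
  y <- c(1, 2, 3, 4, 2, 3)
  g <- c(1, -1, 0, 1, 0, -1) - mean(c(1, -1, 0, 1, 0, -1))
  g <- g - sum(g * (y - mean(y))) / sum((y - mean(y))^2) * (y - mean(y))
  f1 <- fit_ols(cbind(intercept = rep(1, 6)), y)
  f2 <- fit_ols(cbind(intercept = 1, g = g), y)
  a0 <- anova_nested(f1, f2)
  expect_equal(a0$F, 0, tolerance = 1e-10)
  expect_equal(a0$p, 1, tolerance = 1e-10)
  # non-nested designs refused
  fx <- fit_ols(cbind(intercept = 1, x = rnorm(6)), y)
  expect_error(anova_nested(fx, f2), "not nested")
})

test_that("nested ANOVA null p-values are uniform", {
  set.seed(12)
  n <- 48
  C <- rep(0:1, c(14, 34))
  ps <- replicate(2000, {
    G <- rnorm(n); P <- rnorm(n)
    f2 <- fit_ols(cbind(intercept = 1, C = C), P)
    f3 <- fit_ols(cbind(intercept = 1, G = G, C = C), P)
    anova_nested(f2, f3)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("model family recovers planted structure on constructed fixtures", {
  # pure class-driven fixture: zero within-class covariance by symmetry
  expr <- matrix(c(-1, 0, 1, 9, 10, 11), 1, 6,
                 dimnames = list("g", paste0("t", 1:6)))
  props <- matrix(c(0, 0.3, 0, 1, 1.3, 1), 6, 1,
                  dimnames = list(paste0("t", 1:6), "p_g"))
  cls <- stats::setNames(rep(c("excitatory", "inhibitory"), each = 3),
                         paste0("t", 1:6))
  panel <- ct_panel(expr, props, cls,
                    pairs = data.frame(gene = "g", property = "p_g"))
  fits <- fit_gene_property(panel, "g", "p_g")
  cond <- fits[fits$model == "conditional", ]
  expect_equal(cond$beta, 0, tolerance = 1e-12)
  expect_equal(cond$F, 0, tolerance = 1e-12)
  expect_equal(cond$p, 1)
  ind <- fits[fits$model == "independent", ]
  expect_gt(ind$beta, 0)
  expect_equal(cond$delta_expr, 10)  # inhibitory - excitatory mean log2

  # noiseless additive fixture: P = 1.5 G + 2 1[inh]
  set.seed(13)
  G2 <- rnorm(12, 5)
  C2 <- rep(0:1, each = 6)
  P2 <- 1.5 * G2 + 2 * C2
  expr2 <- matrix(G2, 1, 12, dimnames = list("g", paste0("t", 1:12)))
  props2 <- matrix(P2, 12, 1, dimnames = list(paste0("t", 1:12), "p_g"))
  cls2 <- stats::setNames(ifelse(C2 == 1, "inhibitory", "excitatory"),
                          paste0("t", 1:12))
  panel2 <- ct_panel(expr2, props2, cls2)
  fits2 <- fit_gene_property(panel2, "g", "p_g")
  expect_equal(fits2$beta[fits2$model == "conditional"], 1.5, tolerance = 1e-10)
  expect_equal(fits2$p[fits2$model == "interaction"], 1)
})

test_that("interaction-derived per-class slopes equal separate per-class fits", {
  # exact planted case
  G <- c(1, 2, 3, 4, 1, 2, 3, 4)
  C <- rep(0:1, each = 4)
  P <- ifelse(C == 0, G, -G)
  f4 <- fit_ols(cbind(intercept = 1, G = G, C = C, GxC = G * C), P)
  sl <- within_class_slopes(f4)
  expect_equal(unname(sl), c(1, -1), tolerance = 1e-12)
  # random instances vs per-class OLS oracle
  set.seed(14)
  for (i in 1:30) {
    n_e <- sample(4:10, 1); n_i <- sample(4:10, 1)
    G <- rnorm(n_e + n_i); C <- rep(0:1, c(n_e, n_i)); P <- rnorm(n_e + n_i)
    f4 <- fit_ols(cbind(intercept = 1, G = G, C = C, GxC = G * C), P)
    sl <- within_class_slopes(f4)
    oe <- oracle_ols(cbind(1, G[C == 0]), P[C == 0])$coef[2]
    oi <- oracle_ols(cbind(1, G[C == 1]), P[C == 1])$coef[2]
    expect_equal(unname(sl[["slope_exc"]]), unname(oe), tolerance = 1e-10)
    expect_equal(unname(sl[["slope_inh"]]), unname(oi), tolerance = 1e-10)
    # interaction coefficient = slope difference
    expect_equal(unname(f4$coef[["GxC"]]), unname(sl[["slope_inh"]] - sl[["slope_exc"]]),
                 tolerance = 1e-10)
  }
})

test_that("conditional beta obeys the Frisch-Waugh identity", {
  set.seed(15)
  for (i in 1:20) {
    n <- 30
    G <- rnorm(n); C <- rbinom(n, 1, 0.5); P <- rnorm(n)
    if (length(unique(C)) < 2) next
    f3 <- fit_ols(cbind(intercept = 1, G = G, C = C), P)
    demean <- function(v) v - ave(v, C)
    fw <- sum(demean(G) * demean(P)) / sum(demean(G)^2)
    expect_equal(unname(f3$coef[["G"]]), fw, tolerance = 1e-10)
  }
})

test_that("class effect test equals the pooled-variance two-sample t-test", {
  set.seed(16)
  panel <- make_tiny_panel(n_exc = 6, n_inh = 8)
  ct <- class_effect_test(panel, "p_g01")
  P <- panel$props[, "p_g01"]
  tt <- stats::t.test(P[panel$class == "inhibitory"],
                      P[panel$class == "excitatory"], var.equal = TRUE)
  expect_equal(ct$F, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(ct$p, tt$p.value, tolerance = 1e-10)
  # no effect: equal class means with within-class variance
  expr <- matrix(rnorm(8, 5), 1, 8, dimnames = list("g", paste0("t", 1:8)))
  props <- matrix(rep(c(-1, 1), 4), 8, 1,
                  dimnames = list(paste0("t", 1:8), "p"))
  cls <- stats::setNames(rep(c("excitatory", "inhibitory"), each = 4),
                         paste0("t", 1:8))
  pan0 <- ct_panel(expr, props, cls)
  ct0 <- class_effect_test(pan0, "p")
  expect_equal(ct0$F, 0, tolerance = 1e-12)
  expect_equal(ct0$p, 1)
})

test_that("bh_fdr reproduces the rank formula, handles ties, rejects bad input", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.001, 0.5, 0.9)), c(0.003, 0.75, 0.9))
  # ties share a q; order invariance; p.adjust as an independent cross-check
  set.seed(17)
  for (i in 1:20) {
    p <- sample(round(runif(40), 2), 60, replace = TRUE)  # forces ties
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_equal(q, stats::p.adjust(p, method = "BH"))
    perm <- sample(60)
    expect_equal(bh_fdr(p[perm]), q[perm])
    expect_true(all(tapply(q, p, function(v) length(unique(v))) == 1))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("relationship classification follows the q-value decision table", {
  cl <- classify_relationship(
    q_independent = c(0.05, 0.5, 0.05, 1, 0.5, 0.05),
    q_conditional = c(0.5, 0.05, 0.05, 1, 0.5, 0.05),
    q_interaction = c(0.5, 0.5, 0.5, 1, 0.05, 0.05))
  expect_identical(cl$category,
                   c("class_driven", "non_class_driven_obscured",
                     "non_class_driven_shared", "none",
                     "interaction_only", "conditional_and_interaction"))
  expect_identical(cl$interaction_significant,
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_error(classify_relationship(NA_real_, 0.5), "non-missing")
})

test_that("screen q-values are order-invariant and translation-invariant", {
  set.seed(18)
  sim <- simulate_celltype_panel(genes_per_scenario = c(null = 10, shared = 10),
                                 cells_per_type = 2, seed = 21)
  panel <- suppressMessages(summarize_simulated_panel(sim))
  scr <- screen(panel, fdr_family = "model")
  # permuting the pair order leaves q-values per pair unchanged
  perm <- sample(nrow(panel$pairs))
  scr_p <- screen(panel, pairs = panel$pairs[perm, ], fdr_family = "model")
  key <- function(s) paste(s$fits$gene, s$fits$property, s$fits$model)
  expect_equal(scr_p$fits$q[order(key(scr_p))], scr$fits$q[order(key(scr))])
  # shifting every log2 value by one unit (doubling expression) changes nothing
  panel2 <- panel; panel2$expr <- panel$expr + 1
  scr_s <- screen(panel2, fdr_family = "model")
  expect_equal(scr_s$fits$p, scr$fits$p, tolerance = 1e-10)
  expect_equal(scr_s$fits$beta, scr$fits$beta, tolerance = 1e-10)
})

test_that("top-gene selection applies the exclusion rule and deterministic ties", {
  sim <- simulate_celltype_panel(genes_per_scenario = c(obscured = 10, shared = 5),
                                 cells_per_type = 2, seed = 22)
  panel <- suppressMessages(summarize_simulated_panel(sim))
  scr <- screen(panel, fdr_family = "model")
  # exhaustive filter-and-sort oracle over the calls table
  calls <- scr$calls
  cond <- scr$fits[scr$fits$model == "conditional", ]
  for (prop in calls$property[1:3]) {
    sel <- select_top_genes(scr, prop, k = 3)
    sub <- calls[calls$property == prop, ]
    beta <- abs(cond$beta[match(sub$gene, cond$gene)])
    ok <- !is.na(sub$q_conditional) & sub$q_conditional <= 0.1 &
      !is.na(sub$q_independent) & sub$q_independent > 0.2 &
      !is.na(sub$q_interaction) & sub$q_interaction > 0.2
    oracle <- head(sub$gene[ok][order(sub$q_conditional[ok], -beta[ok],
                                      sub$gene[ok])], 3)
    expect_identical(sel, oracle)
  }
  # a gene significant independently at 0.15 is excluded (0.15 <= 0.2)
  scr2 <- scr
  scr2$calls <- data.frame(gene = c("a", "b"), property = "p",
                           q_independent = c(0.15, 0.5),
                           q_conditional = c(0.01, 0.02),
                           q_interaction = c(0.5, 0.5),
                           category = "x", interaction_significant = FALSE)
  scr2$fits <- data.frame(gene = c("a", "b"), property = "p",
                          model = "conditional", beta = c(1, 1), q = c(0.01, 0.02))
  expect_identical(select_top_genes(scr2, "p"), "b")
  scr2$calls$q_conditional <- c(0.5, 0.5)
  expect_identical(select_top_genes(scr2, "p"), character(0))
})

test_that("interaction coefficient is unrelated to class expression difference", {
  # no class expression shift anywhere: delta_expr is pure noise, so its
  # rank correlation with the interaction coefficient should vanish
  sim <- simulate_celltype_panel(genes_per_scenario = c(null = 250, interaction = 250),
                                 delta = 0, cells_per_type = 2, seed = 23)
  panel <- suppressMessages(summarize_simulated_panel(sim))
  scr <- screen(panel, fdr_family = "model")
  int <- scr$fits[scr$fits$model == "interaction", ]
  rho <- stats::cor(int$delta_expr, int$beta, method = "spearman")
  expect_lt(abs(rho), 0.1)
})
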