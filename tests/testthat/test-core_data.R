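test_that("expression matrix round-trips through TSV bit-exactly", {
  set.seed(1)
  m <- matrix(round(abs(rnorm(30, 50, 20)), 6), 6, 5,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:5)))
  em <- expression_matrix(m, "CPM")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(em, path)
  back <- read_expression_matrix(path, "CPM")
  expect_identical(back$values, em$values)
  expect_identical(back$unit, "CPM")
})

test_that("expression matrix rejects malformed input", {
  m <- matrix(c(1, 2, -3, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_error(expression_matrix(m, "CPM"), "negative.*g1.*c2")
  m2 <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g1"), c("c1", "c2")))
  storage.mode(m2) <- "double"
  expect_error(expression_matrix(m2, "CPM"), "duplicate gene")
  m3 <- matrix(as.numeric(1:4), 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c1")))
  expect_error(expression_matrix(m3, "CPM"), "duplicate cell")
})

test_that("log transform anchors, inverts, and refuses double application", {
  m <- expression_matrix(matrix(c(1, 0, 3, 7), 2, 2,
                                dimnames = list(c("g1", "g2"), c("c1", "c2"))),
                         "CPM")
  lg <- log_transform_expression(m)
  expect_equal(lg$values[1, 1], 1.0)   # log2(1+1)
  expect_equal(lg$values[2, 1], 0.0)   # log2(0+1)
  expect_identical(lg$unit, "log2CPM1")
  expect_error(log_transform_expression(lg), "already log")

  set.seed(2)
  r <- expression_matrix(matrix(runif(50, 0, 100), 10, 5,
                                dimnames = list(paste0("g", 1:10),
                                                paste0("c", 1:5))), "CPM")
  rl <- log_transform_expression(r)
  expect_equal(2^rl$values - 1, r$values, tolerance = 1e-12)
})

test_that("QC filter keeps only qc-passing reporter-positive neurons, order preserved", {
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:10),
    dataset_id = "d",
    class_label = c(rep("excitatory", 4), rep("inhibitory", 4), "unknown", "unknown"),
    reporter_positive = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    qc_pass = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  out <- suppressMessages(qc_filter_cells(cells))
  # brute-force enumeration of the expected survivors
  expected <- cells$cell_id[cells$qc_pass & cells$reporter_positive &
                              cells$class_label != "unknown"]
  expect_identical(out$cell_id, expected)
  expect_identical(out$cell_id, c("c01", "c04", "c05", "c06"))
  all_pass <- cells[cells$cell_id %in% expected, ]
  expect_identical(suppressMessages(qc_filter_cells(all_pass))$cell_id,
                   all_pass$cell_id)
})

test_that("property transforms: log10 set, sag validity window, non-positive handling", {
  meta <- data.frame(property = c("rheobase", "sag", "ap_half_width"),
                     transform = c("log10", "none", "none"),
                     family = "ephys")
  props <- data.frame(
    cell_id = paste0("c", 1:5),
    rheobase = c(100, 10, 1000, -5, 100),
    sag = c(0.1, 0.2, 0.3, 0.4, 0.5),
    ap_half_width = 1:5,
    vm_for_sag = c(-100, -85, -100, -100, -111),
    resting_potential = c(-70, -70, -85, -75, -70))
  out <- suppressMessages(suppressWarnings(transform_properties(props, meta)))
  expect_equal(out$rheobase[1], 2.0)            # log10(100)
  expect_true(is.na(out$rheobase[4]))           # non-positive -> missing
  # rule table: invalid iff vm outside [-110,-90] or resting < -80
  expect_true(is.na(out$sag[2]))                # vm -85 out of window
  expect_true(is.na(out$sag[3]))                # resting -85 < -80
  expect_true(is.na(out$sag[5]))                # vm -111 out of window
  expect_equal(out$sag[c(1, 4)], c(0.1, 0.4))   # valid cells untouched
  expect_equal(out$ap_half_width, 1:5)          # untransformed column intact
  expect_error(transform_properties(props, data.frame(property = "nope",
                                                      transform = "log10",
                                                      family = "ephys")),
               "absent")
})

test_that("branchiness is branch count per micron with guarded denominator", {
  expect_equal(derive_branchiness(50, 1000), 0.05)
  expect_equal(derive_branchiness(0, 1000), 0)
  expect_warning(out <- derive_branchiness(10, 0), "non-positive")
  expect_true(is.na(out))
  set.seed(3)
  nb <- rpois(20, 40); tl <- runif(20, 100, 5000)
  expect_equal(derive_branchiness(nb, tl), nb / tl)
})

test_that("cell-type assignment applies 6/3 minima per analysis", {
  # 3 Cre lines x up to 2 layers, hand-enumerated retention
  grouping <- data.frame(
    type_id = c("A_L1", "A_L2", "B", "B", "C_L1", "C_L2"),
    cre_line = c("A", "A", "B", "B", "C", "C"),
    layer = c("L1", "L2", "L1", "L2", "L1", "L2"),
    class_label = c("excitatory", "excitatory", "inhibitory", "inhibitory",
                    "inhibitory", "inhibitory"))
  mk <- function(n, cre, layer, cls, rna, eph, mor) {
    data.frame(cell_id = paste(cre, layer, seq_len(n), sep = "_"),
               cre_line = cre, layer = layer, class_label = cls,
               has_rnaseq = rna, has_ephys = eph, has_morph = mor)
  }
  cells <- rbind(
    mk(10, "A", "L1", "excitatory", TRUE, TRUE, FALSE),   # retained ephys
    mk(5,  "A", "L2", "excitatory", TRUE, TRUE, TRUE),    # 5 < 6: morph only
    mk(8,  "B", "L1", "inhibitory", TRUE, TRUE, TRUE),    # merged with L2
    mk(3,  "B", "L2", "inhibitory", TRUE, FALSE, TRUE),
    mk(100, "C", "L1", "inhibitory", TRUE, FALSE, FALSE), # no ephys/morph cells
    mk(3,  "C", "L2", "inhibitory", TRUE, TRUE, TRUE))    # 3 = morph boundary
  types <- suppressMessages(assign_cell_types(cells, grouping))
  get <- function(id, col) types[types$type_id == id, col]
  expect_true(get("A_L1", "retained_ephys"))
  expect_false(get("A_L1", "retained_morph"))
  expect_false(get("A_L2", "retained_ephys"))   # 5 ephys cells, needs 6
  expect_true(get("A_L2", "retained_morph"))
  expect_true(get("B", "retained_ephys"))       # 8 ephys, 11 rnaseq after merge
  expect_true(get("B", "retained_morph"))
  expect_false(get("C_L1", "retained_ephys"))
  expect_true(get("C_L2", "retained_morph"))    # boundary inclusive at 3
  expect_false(get("C_L2", "retained_ephys"))
  expect_identical(sum(types$retained_morph), 3L)  # A_L2, B, C_L2

  orphan <- rbind(cells, data.frame(cell_id = "zz", cre_line = "Z", layer = "L9",
                                    class_label = "excitatory", has_rnaseq = TRUE,
                                    has_ephys = TRUE, has_morph = TRUE))
  expect_error(suppressMessages(assign_cell_types(orphan, grouping)), "zz")
})

test_that("summarization takes mean of logs per type and honours missingness", {
  vals <- matrix(c(1, 3, 2, 2, 0, 4), 1, 6,
                 dimnames = list("g1", paste0("c", 1:6)))
  em <- expression_matrix(vals, "log2CPM1")
  cells <- data.frame(cell_id = paste0("c", 1:6), cre_line = rep(c("A", "B"), each = 3),
                      layer = "L", class_label = rep(c("excitatory", "inhibitory"), each = 3),
                      has_rnaseq = TRUE, has_ephys = TRUE, has_morph = FALSE)
  grouping <- data.frame(type_id = c("A", "B"), cre_line = c("A", "B"),
                         layer = "L", class_label = c("excitatory", "inhibitory"))
  types <- suppressMessages(assign_cell_types(cells, grouping, min_ephys = 3, min_morph = 3))
  props <- data.frame(cell_id = paste0("c", 1:6),
                      p1 = c(1, 2, NA, 4, 5, 6),
                      p2 = c(NA, NA, NA, 1, 1, 1))
  panel <- summarize_to_cell_types(em, props, types)
  expect_equal(unname(panel$expr["g1", ]), c(2, 2))        # mean of logs
  expect_equal(unname(panel$props["A", "p1"]), 1.5)        # NA excluded pairwise
  expect_true(is.na(panel$props["A", "p2"]))               # zero contributors -> NA
  expect_equal(unname(panel$props["B", "p2"]), 1)
  # permuting cells within a type leaves the profile unchanged
  perm <- c("c3", "c1", "c2", "c6", "c5", "c4")
  em2 <- expression_matrix(vals[, perm, drop = FALSE], "log2CPM1")
  panel2 <- summarize_to_cell_types(em2, props, types)
  expect_equal(panel2$expr, panel$expr)
  expect_equal(panel2$props, panel$props)
  # raw-unit input refused
  expect_error(summarize_to_cell_types(expression_matrix(vals, "CPM"),
                                       props, types), "log-transformed")
})

test_that("gene expression filter matches a brute-force scan and is monotone", {
  set.seed(4)
  expr <- matrix(runif(200 * 20, 0, 3), 200, 20,
                 dimnames = list(sprintf("g%03d", 1:200), sprintf("t%02d", 1:20)))
  props <- matrix(0, 20, 1, dimnames = list(colnames(expr), "p"))
  cls <- stats::setNames(rep(c("excitatory", "inhibitory"), 10), colnames(expr))
  panel <- ct_panel(expr, props, cls)
  kept <- suppressMessages(filter_genes_by_expression(panel, 1.0, 10))
  brute <- rownames(expr)[apply(expr, 1, function(v) sum(v >= 1.0) >= 10)]
  expect_identical(kept, brute)
  # monotone: loosening either threshold never drops a kept gene
  kept_lo_level <- suppressMessages(filter_genes_by_expression(panel, 0.5, 10))
  kept_lo_types <- suppressMessages(filter_genes_by_expression(panel, 1.0, 5))
  expect_true(all(kept %in% kept_lo_level))
  expect_true(all(kept %in% kept_lo_types))
  expect_error(filter_genes_by_expression(panel, 1.0, 21), "exceeds")
})
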