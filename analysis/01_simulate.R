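#!/usr/bin/env Rscript
# Generate the synthetic study data used by the downstream analyses:
# a 48-type cell panel with all five planted gene-property scenarios,
# paired panels for the consistency analysis, and a 5-dataset PatchSeq-like
# bundle.  Everything is seeded; rerunning reproduces the files exactly.

suppressMessages(library(neurocorr))
seed <- 17
out <- "results/01_simulate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_celltype_panel(
  genes_per_scenario = c(null = 200, class_driven = 100, shared = 100,
                         obscured = 100, interaction = 100),
  seed = seed)
write_expression_matrix(sim$expr, file.path(out, "panel_expr_cpm.tsv"))
write_tsv_stable(sim$props, file.path(out, "panel_props.tsv"))
write_tsv_stable(sim$cells, file.path(out, "panel_cells.tsv"))
write_tsv_stable(sim$truth, file.path(out, "panel_truth.tsv"))
write_tsv_stable(sim$pairs, file.path(out, "panel_pairs.tsv"))

cat(sprintf("panel: %d genes x %d cells (%d types, 14 exc / 34 inh)\n",
            nrow(sim$expr$values), ncol(sim$expr$values),
            length(unique(sim$cells$cre_line))))
cat("scenario counts:\n")
print(table(sim$truth$scenario))

cat("done; outputs under", out, "\n")
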