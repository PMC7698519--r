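#!/usr/bin/env Rscript
# Stage 2: exposure-slope quantification and fold-change calling.
#
# For each simulated comparison: fit per-peptide linear regressions of
# intensity on exposure time, drop nonlinear (R^2 < 0.90) and undetectable
# (slope <= 0) peptides plus internal controls, and compute replicate-averaged
# fold changes with the 30% differential thresholds (FC >= 1.30 or <= 0.70).

suppressPackageStartupMessages({
  library(kinomeRank)
  library(readr)
})

out <- "results"
catalog <- read_tsv(file.path(out, "catalog.tsv"), show_col_types = FALSE)

for (ctx in c("LINE_A", "LINE_B", "LINE_C")) {
  path <- file.path(out, "runs", paste0(ctx, "_intensities.tsv"))
  stopifnot(nrow(validate_table(path, "run")) == 0)
  intensities <- read_run_tsv(path)
  fits <- fit_run_slopes(intensities)
  retained <- filter_peptides(fits, r2_min = 0.90, catalog = catalog)
  pfc <- compute_fold_change(fits, retained, fc_up = 1.30, fc_down = 0.70)
  write_tsv(pfc, file.path(out, paste0(ctx, "_peptides.tsv")))
  cat(sprintf("%s: %d/%d peptides retained, %d differential (%d up, %d down)\n",
              ctx, length(retained), nrow(catalog),
              sum(pfc$is_differential),
              sum(pfc$is_differential & pfc$fc >= 1.30),
              sum(pfc$is_differential & pfc$fc <= 0.70)))
}
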