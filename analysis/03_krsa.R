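#!/usr/bin/env Rscript
# Stage 3: kinome random-sampling analysis.
#
# Scores each kinase family by comparing its observed hit count among the
# differential peptides to an empirical null from 3000 uniform draws of
# equally sized peptide sets out of the 196-spot universe; attaches Z-scores,
# directionality (mean log2FC of the family's differential peptides) and
# inclusive percentile ranks.

suppressPackageStartupMessages({
  library(kinomeRank)
  library(readr)
})

seed <- 2024L
out <- "results"
catalog <- read_tsv(file.path(out, "catalog.tsv"), show_col_types = FALSE)
map <- read_map_tsv(file.path(out, "map.tsv"))
fam_map <- collapse_to_families(map)

for (ctx in c("LINE_A", "LINE_B", "LINE_C")) {
  pfc <- read_tsv(file.path(out, paste0(ctx, "_peptides.tsv")),
                  show_col_types = FALSE)
  cfg <- krsa_config(iterations = 3000L,
                     seed = seed + match(ctx, c("LINE_A", "LINE_B", "LINE_C")))
  res <- krsa(pfc, fam_map, catalog$peptide_id, cfg)
  write_tsv(res, file.path(out, paste0(ctx, "_krsa.tsv")))
  top <- res[which.max(abs(res$z_score)), ]
  cat(sprintf("%s: m = %d differential peptides; top family %s (Z = %.1f, %s)\n",
              ctx, sum(pfc$is_differential), top$family_id, top$z_score,
              top$direction))
}
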