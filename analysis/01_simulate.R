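#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Builds a synthetic tyrosine-kinase chip (196 peptides, 3 internal controls),
# a kinase-peptide map (40 kinases in families), and three case-vs-control
# comparisons emulating three tumor cell lines, each with its own spiked
# (differentially active) kinases. Everything downstream reads the files this
# stage writes under results/.

suppressPackageStartupMessages({
  library(kinomeRank)
  library(readr)
  library(tibble)
})

seed <- 2024L
out <- "results"
dir.create(file.path(out, "runs"), recursive = TRUE, showWarnings = FALSE)

catalog <- generate_catalog(seed = seed)
map <- generate_map(catalog, n_kinases = 40L, mean_peptides = 8, seed = seed)
write_tsv(catalog, file.path(out, "catalog.tsv"))
write_map_tsv(map, file.path(out, "map.tsv"))
cat(sprintf("chip: %d peptides (%d internal controls), %d kinases in %d families\n",
            nrow(catalog), sum(catalog$is_internal_control),
            length(unique(map$kinase_id)), length(unique(map$family_id))))

# Per-line truths: one strongly increased kinase, one decreased kinase, and a
# line sharing a spike with line A (so group-level aggregation has signal).
spikes <- list(
  LINE_A = tibble(kinase_id = "KIN01", effect_log2fc = 1.5),
  LINE_B = tibble(kinase_id = "KIN05", effect_log2fc = -1.2),
  LINE_C = tibble(kinase_id = c("KIN01", "KIN10"), effect_log2fc = c(1.0, 0.8))
)

for (ctx in names(spikes)) {
  truth <- synthetic_truth(
    spiked_kinases = spikes[[ctx]],
    noise_sd = 20, nonlinear_fraction = 0.05, undetectable_fraction = 0.03,
    seed = seed + match(ctx, names(spikes))
  )
  run <- simulate_run(catalog, map, truth)
  write_run(run, file.path(out, "runs"), name = ctx)
  cat(sprintf("%s: %d intensity rows, spiked %s\n", ctx,
              nrow(run$intensities),
              paste(spikes[[ctx]]$kinase_id, collapse = ", ")))
}
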