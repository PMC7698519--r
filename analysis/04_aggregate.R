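#!/usr/bin/env Rscript
# Stage 4: multi-pipeline rank aggregation.
#
# Converts each pipeline's native scores to inclusive percentile ranks and
# combines them per cell line and per cell-line group into unweighted and
# weighted (sum / total pipelines) consensus rankings, reported as top-10
# tables. The three external pipelines' score tables are simulated from the
# same spiked truths via simulate_pipeline_scores(); the resampling pipeline
# uses the stage-3 results.

suppressPackageStartupMessages({
  library(kinomeRank)
  library(readr)
  library(dplyr)
  library(tibble)
})

seed <- 2024L
out <- "results"
map <- read_map_tsv(file.path(out, "map.tsv"))
families <- distinct(map, kinase_id, family_id)

spikes <- list(
  LINE_A = tibble(kinase_id = "KIN01", effect_log2fc = 1.5),
  LINE_B = tibble(kinase_id = "KIN05", effect_log2fc = -1.2),
  LINE_C = tibble(kinase_id = c("KIN01", "KIN10"), effect_log2fc = c(1.0, 0.8))
)

all_scores <- list()
for (ctx in names(spikes)) {
  kres <- read_tsv(file.path(out, paste0(ctx, "_krsa.tsv")),
                   show_col_types = FALSE)
  ctx_seed <- seed + match(ctx, names(spikes))
  truth <- synthetic_truth(spiked_kinases = spikes[[ctx]], seed = ctx_seed)
  native <- simulate_pipeline_scores(map, truth, ctx, seed = ctx_seed)
  all_scores[[ctx]] <- bind_rows(
    adapter_krsa(kres, families, ctx),
    adapter_uka(native$uka),
    adapter_ptmsea(native$ptmsea),
    adapter_kea3(native$kea3)
  )
}

scores <- score_percentiles(bind_rows(all_scores))
groups <- list(`Group-AC` = c("LINE_A", "LINE_C"),
               All = c("LINE_A", "LINE_B", "LINE_C"))
scores <- bind_rows(scores, aggregate_groups(scores, groups))

rankings <- aggregate_rankings(scores, total_pipelines = 4L, families = families)
top_unw <- top_k_table(rankings, k = 10L, sort_key = "unweighted_avg")
top_wt <- top_k_table(rankings, k = 10L, sort_key = "weighted_avg")
write_tsv(rankings, file.path(out, "rankings.tsv"))
write_tsv(top_unw, file.path(out, "top10_unweighted.tsv"))
write_tsv(top_wt, file.path(out, "top10_weighted.tsv"))

for (ctx in unique(top_unw$context_id)) {
  lead <- top_unw[top_unw$context_id == ctx, ][1, ]
  cat(sprintf("%s: top kinase %s (family %s), average percentile %d%%\n",
              ctx, lead$kinase_id, lead$family_id, lead$unweighted_avg))
}
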