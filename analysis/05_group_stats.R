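#!/usr/bin/env Rscript
# Stage 5: assumption-gated group comparison of the study cells, mirroring
# the reporting convention for crystallized-lipid tables: per-metric
# Brown-Forsythe gate, then ordinary two-way ANOVA + Tukey HSD or Welch
# ANOVA + Dunnett T3 across the four cells, with compact-letter displays
# at alpha 0.05. Requires results/04_metrics.tsv (run stage 4 first).

library(voidnet)
met <- read.table("results/04_metrics.tsv", sep = "\t", header = TRUE,
                  check.names = FALSE)
env <- new.env(); sys.source("analysis/01_simulate_phantoms_common.R", env)

out_rows <- list()
for (metric in c("v", "z", "r43_pore_um")) {
  groups <- lapply(env$cells, function(cl) {
    des <- env$cell_design[env$cell_design$cell == cl, ]
    sample_group("CB", des$emulsifier, des$shear_type,
                 replicate_values = met[[metric]][met$cell == cl])
  })
  cr <- compare_groups(groups, alpha = 0.05, metric_name = metric)
  cat("\n==", metric, "==  branch:", cr$branch, "\n")
  gs <- cr$group_summary
  gs$letter <- cr$letters[gs$group]
  print(gs, row.names = FALSE, digits = 4)
  out_rows[[metric]] <- data.frame(metric = metric, gs,
                                   branch = cr$branch)
}
tab <- do.call(rbind, out_rows)
write.table(tab, "results/05_group_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nGroups sharing a letter are not significantly different",
    "(alpha <= 0.05).\nTable written to results/05_group_stats.tsv\n")
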