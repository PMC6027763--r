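#!/usr/bin/env Rscript
# Study-level statistics on the quantified measurements: mosaic
# averaging, isocortex means, demographic summaries of the 20-case
# cohort table, normality screen, two-way ANOVA (Braak group x region)
# with Bonferroni cell-mean contrasts, and fold change versus controls.

suppressMessages(library(tauquant))

out <- "results"
m <- read_measurements(file.path(out, "measurements.csv"))

## cohort demographics (printed-precision group means)
summ <- summarize_cases(example_case_table())
write.csv(summ, file.path(out, "case_summary.csv"), row.names = FALSE)
cat("cohort group means:\n"); print(summ)

## aggregate: mosaics, then isocortex
av <- average_mosaics(m)
av_iso <- isocortex_mean(av)
write.csv(av_iso, file.path(out, "measurements_aggregated.csv"),
          row.names = FALSE)

## normality screen per (group, region) cell
ks <- do.call(rbind, lapply(split(av, list(av$braak_group, av$region)),
  function(cell) {
    if (nrow(cell) < 5) return(NULL)
    k <- ks_normality(cell$ir_area_percent)
    data.frame(braak_group = cell$braak_group[1], region = cell$region[1],
               D = k$statistic, p = k$p)
  }))
write.csv(ks, file.path(out, "normality.csv"), row.names = FALSE)
cat(sprintf("\nnormality screen: %d of %d cells with Lilliefors p < 0.05\n",
            sum(ks$p < 0.05), nrow(ks)))

## factorial ANOVA + post-hoc on the regional values
a <- two_way_anova(av)
write.csv(a$table, file.path(out, "anova.csv"), row.names = FALSE)
if (!is.null(a$post_hoc))
  write.csv(a$post_hoc, file.path(out, "posthoc.csv"), row.names = FALSE)
cat("\ntwo-way ANOVA (type", a$type, "):\n"); print(a$table, digits = 4)
vs <- a$post_hoc[a$post_hoc$family == "braak_group_within_region" &
                 a$post_hoc$comparison == "control vs V_VI", ]
cat("\ncontrol vs V/VI within region (Bonferroni):\n")
print(vs[, c("stratum", "estimate", "p_adj", "significant")], digits = 3)

## fold change vs controls
fc <- fold_change(av)
write.csv(fc, file.path(out, "foldchange.csv"), row.names = FALSE)
cat("\nfold change vs controls (V/VI rows):\n")
print(fc[fc$braak_group == "V_VI", ], digits = 3)
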