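#!/usr/bin/env Rscript
# Bar charts (group mean + SEM) of percent immunoreactive area per
# region and Braak group, and the fold-change progression per region --
# the standard presentation for staged-pathology studies.

suppressMessages({
  library(tauquant)
  library(ggplot2)
})

out <- "results"
fig_dir <- file.path(out, "figures")
dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)

av <- read_measurements(file.path(out, "measurements_aggregated.csv"))
av$braak_group <- factor(av$braak_group,
                         levels = c("control", "I_II", "III_IV", "V_VI"))
av$region <- factor(av$region,
                    levels = c("Isocortex", "TeCtx", "FrCtx", "CiCtx",
                               "OcCtx", "TEntR"))

bars <- aggregate(ir_area_percent ~ braak_group + region, av, mean)
bars$sem <- aggregate(ir_area_percent ~ braak_group + region, av,
                      sem)$ir_area_percent

p1 <- ggplot(bars, aes(braak_group, ir_area_percent, fill = braak_group)) +
  geom_col(colour = "black", width = 0.7, show.legend = FALSE) +
  geom_errorbar(aes(ymin = ir_area_percent,
                    ymax = ir_area_percent + sem), width = 0.25) +
  facet_wrap(~region, nrow = 2, scales = "free_y") +
  scale_fill_brewer(palette = "Greys") +
  labs(x = "Braak stage group", y = "IR area (%)",
       title = "Marker-positive area by region and stage (mean + SEM, n = 5)") +
  theme_classic(base_size = 11)
ggsave(file.path(fig_dir, "ir_area_by_region.png"), p1,
       width = 9, height = 5.5, dpi = 150)

fc <- read.csv(file.path(out, "foldchange.csv"))
fc$braak_group <- factor(fc$braak_group,
                         levels = c("control", "I_II", "III_IV", "V_VI"))
p2 <- ggplot(fc, aes(braak_group, fold_change, group = region,
                     colour = region)) +
  geom_line() + geom_point() +
  labs(x = "Braak stage group", y = "Fold change vs controls",
       title = "Signal increase relative to control sections") +
  theme_classic(base_size = 11)
ggsave(file.path(fig_dir, "foldchange_progression.png"), p2,
       width = 7, height = 4.5, dpi = 150)

cat("figures written to", fig_dir, "\n")
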