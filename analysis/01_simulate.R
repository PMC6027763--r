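#!/usr/bin/env Rscript
# Simulate the staged study used throughout the analysis: 5 cases per
# Braak group (control, I/II, III/IV, V/VI), 5 cortical regions per case
# (TeCtx, FrCtx, CiCtx, OcCtx, TEntR), two mosaic fields per region,
# with stage-increasing tangle/thread burdens and constant lipofuscin.
#
# Sections are fully reproducible from the master seed, so only the case
# table, a burden-design snapshot, one example section (multi-page TIFF)
# and its ground-truth masks are written; later scripts regenerate the
# sections in memory from the same seed.

suppressMessages(library(tauquant))

master_seed <- 42L
out <- "results"
dir.create(file.path(out, "example_section"), showWarnings = FALSE,
           recursive = TRUE)

design <- default_study_design()
write.csv(design, file.path(out, "study_design.csv"), row.names = FALSE)

study <- generate_study(design, n_cases_per_group = 5L, seed = master_seed,
                        n_mosaics = 2L)
write.csv(study$case_table, file.path(out, "case_table.csv"),
          row.names = FALSE)

# one high-burden example section for inspection
ex <- which(study$case_table$braak_group == "V_VI" &
            study$case_table$region == "TEntR")[1]
sec <- study$sections[[ex]]
write_section_tiff(sec, file.path(out, "example_section", "section.tif"))
write_ground_truth(sec, file.path(out, "example_section"),
                   study$case_table$section_id[ex])

cat(sprintf("simulated %d sections (%d cases x 5 regions x 2 mosaics)\n",
            length(study$sections),
            length(unique(study$case_table$case_id))))
fr <- sec$ground_truth$true_area_fraction
cat("example V/VI TEntR section true fractions:",
    paste(sprintf("%s=%.4f", names(fr), fr), collapse = " "), "\n")
cat("case table written to", file.path(out, "case_table.csv"), "\n")
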