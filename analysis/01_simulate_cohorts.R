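#!/usr/bin/env Rscript
# Stage 1: generate the synthetic discovery cohort.
#
# The generator emulates the blood study design the workflow targets:
# 8 cases vs 21 controls aged 3-15, a 100-CpG planted signature at
# |delta beta| = 0.15, six-cell-type leukocyte mixtures, age/sex covariate
# effects, logit-scale noise (SD 0.3), and planted QC-failing probes in all
# six removal categories. Ground truth is written alongside the data so
# every later stage can be audited.

library(episig)

seed <- 101
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
sim <- simulate_cohort(cfg, cohort = "discovery")

write_beta_matrix(sim$beta, file.path(out, "discovery_beta.tsv"))
write_detection_p(sim$detp, file.path(out, "discovery_detp.tsv"))
write_sample_sheet(sim$sheet, file.path(out, "discovery_sheet.tsv"))
write_probe_annotation(sim$annotation, file.path(out, "probe_annotation.tsv"))
write_signature(sim$truth$signature, file.path(out, "truth_signature.tsv"))
saveRDS(sim, file.path(out, "discovery_sim.rds"))  # full object for later stages

cat("Simulated", nrow(sim$beta), "probes x", ncol(sim$beta), "samples\n")
print(cohort_summary(sim$sheet[sim$sheet$group == "case", ]))
print(cohort_summary(sim$sheet[sim$sheet$group == "control", ]))
cat("Planted signature:", nrow(sim$truth$signature), "CpGs,",
    sum(sim$truth$signature$direction == "hyper"), "hypermethylated\n")
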