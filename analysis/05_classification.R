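#!/usr/bin/env Rscript
# Stage 5: SVM probability classification.
#
# Trains the linear-kernel SVM on the discovery cohort at the signature
# probes (features standardized, sigmoid calibration on internal 3-fold
# CV), then scores (a) the discovery samples by leave-one-out
# cross-validation, (b) a fresh validation batch of 8 cases + 200 controls
# carrying the same planted signature, and (c) an "other syndrome"
# specificity cohort whose planted signature is disjoint from the model's
# probes. Scores above 0.5 are called KdVS-like, below 0.5 control-like.

library(episig)

seed <- 101
sim <- readRDS("results/data/discovery_sim.rds")
qc_beta <- read_beta_matrix("results/qc_filtered_beta.tsv")
sig <- read_signature("results/signature.tsv")

model <- train_classifier(qc_beta, sim$sheet$group, sig$probe_id, seed = seed)
save_model(model, "results/model.json")

loo <- cross_validate(qc_beta, sim$sheet$group, sig$probe_id, seed = seed)
cat(sprintf("Leave-one-out on discovery: sensitivity %.2f, specificity %.2f\n",
            attr(loo, "sensitivity"), attr(loo, "specificity")))

# fresh validation batch with the same planted signature
val_cfg <- simulation_config(n_cases = 8, n_controls = 200, seed = seed + 1000)
val <- simulate_cohort(val_cfg, reference = sim$reference,
                       annotation = sim$annotation,
                       signature = sim$truth$signature, cohort = "validation")
vs <- score_samples(model, val$beta)
vs$group <- val$sheet$group
utils::write.table(vs, "results/validation_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("Validation cases score %.1f-%.1f%%; controls %.1f-%.1f%%\n",
            100 * min(vs$score[vs$group == "case"]),
            100 * max(vs$score[vs$group == "case"]),
            100 * min(vs$score[vs$group == "control"]),
            100 * max(vs$score[vs$group == "control"])))

# specificity panel: same generator, signature planted at disjoint probes
clean <- attr(sim$annotation, "clean_pool")
other_sig <- data.frame(
  probe_id = setdiff(clean, sim$truth$signature$probe_id)[
    seq_len(nrow(sim$truth$signature))],
  delta_beta = sim$truth$signature$delta_beta)
other_cfg <- simulation_config(n_cases = 20, n_controls = 0, seed = seed + 2000)
other <- simulate_cohort(other_cfg, reference = sim$reference,
                         annotation = sim$annotation, signature = other_sig,
                         cohort = "classification", prefix = "other")
panel <- specificity_panel(model, list(other_syndrome = other$beta))
utils::write.table(panel, "results/specificity_panel.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("Other-syndrome cohort scores: median %.1f%% (range %.1f-%.1f%%)\n",
            100 * panel$median, 100 * panel$min, 100 * panel$max))

# single-sample classification, as applied to variants of uncertain
# significance: one validation case and one validation control
one_case <- classify_case(model, val$beta[, 1, drop = FALSE])
one_ctrl <- classify_case(model, val$beta[, ncol(val$beta), drop = FALSE])
cat(sprintf("Example VUS-style calls: case sample %.1f%% (%s), control sample %.1f%% (%s)\n",
            100 * one_case$score, one_case$label,
            100 * one_ctrl$score, one_ctrl$label))
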