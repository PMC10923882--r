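#!/usr/bin/env Rscript
# Stage 7: fibroblast cross-tissue comparison.
#
# Simulates a small fibroblast cohort (3 cases vs 7 controls) whose planted
# signature shares a handful of CpGs with the blood signature, runs the
# variance pre-filter (keep probes with beta range > 10%) followed by
# differential methylation, and intersects the resulting tissue signatures
# at the probe and gene level.

library(episig)

seed <- 101
sim <- readRDS("results/data/discovery_sim.rds")
blood_sig <- read_signature("results/signature.tsv")

# fibroblast signature: a few CpGs shared with blood, the rest private
clean <- attr(sim$annotation, "clean_pool")
shared <- utils::head(intersect(blood_sig$probe_id, clean), 3)
set.seed(seed + 7)
private <- sample(setdiff(clean, blood_sig$probe_id), 40)
fib_sig <- data.frame(probe_id = c(shared, private),
                      delta_beta = rep(c(0.2, -0.2),
                                       length.out = length(shared) + 40))
fib_cfg <- simulation_config(n_cases = 3, n_controls = 7, seed = seed + 8,
                             noise_sd = 0.2)
fib <- simulate_cohort(fib_cfg, reference = sim$reference,
                       annotation = sim$annotation, signature = fib_sig,
                       cohort = "discovery", prefix = "fib")
fib$sheet$tissue <- "fibroblast"

# variance pre-filter then differential methylation
vf <- variance_filter(fib$beta, min_range = 0.10)
cat(sprintf("Variance filter: kept %d of %d probes (range > 10%%)\n",
            nrow(vf$beta), nrow(fib$beta)))
res <- dm_analysis(vf$beta, fib$sheet)
fib_called <- select_signature(res, alpha = 0.05, delta = 0.10)
write_signature(fib_called, "results/fibroblast_signature.tsv")
cat(sprintf("Fibroblast signature: %d CpGs at FDR < 0.05, |delta beta| > 0.10\n",
            nrow(fib_called)))

genes <- simulate_gene_annotation(sim$annotation, seed = seed)
blood_genes <- map_genes(blood_sig, sim$annotation, genes)$gene
fib_genes <- map_genes(fib_called, sim$annotation, genes)$gene
ov <- cross_tissue_overlap(blood_sig, fib_called, blood_genes, fib_genes)
cat("Cross-tissue overlap:", length(ov$common_probes), "common CpG(s) and",
    length(ov$common_genes), "common underlying gene(s)\n")
writeLines(c("# common probes", ov$common_probes, "# common genes",
             ov$common_genes), "results/cross_tissue_overlap.txt")

pc <- pca_projection(fib$beta, blood_sig$probe_id)
cat(sprintf("Fibroblasts at blood signature sites: PC1 = %.0f%% of variance\n",
            100 * pc$variance_fraction[1]))
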