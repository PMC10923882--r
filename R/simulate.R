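#' Simulation configuration for synthetic EPIC-like cohorts
#'
#' Bundles every knob of the cohort generator. Defaults mirror the study
#' design the workflow targets: a discovery cohort of 8 cases and 21
#' sex/age-matched controls aged 3-15 years, a planted signature of 100 CpGs
#' at a 15% beta difference, logit-scale noise (SD 0.3), and a blood
#' leukocyte mixture dominated by neutrophils.
#'
#' @param n_probes total probes on the synthetic array.
#' @param n_cases,n_controls cohort sizes.
#' @param n_signature_probes CpGs carrying a planted case/control difference.
#' @param effect_size_range range of |delta beta| for planted effects
#'   (drawn uniformly; both endpoints equal gives a fixed effect size).
#' @param noise_sd SD of logit-scale measurement noise (0 disables noise).
#' @param dirichlet_concentration named per-cell-type Dirichlet concentration
#'   for sample mixing weights.
#' @param age_range sampling range of ages in years.
#' @param n_age_effect_probes,age_slope probes with a linear age trend and
#'   its slope (beta per year; sign randomized per probe).
#' @param n_sex_effect_probes,sex_effect probes with an additive male/female
#'   offset (beta units; sign randomized per probe).
#' @param qc_fail named counts of planted QC-failing probes per category:
#'   detection, snp, cross_reactive, extreme_beta, non_cpg, sex_chromosome.
#' @param seed integer seed; all draws flow from this single stream.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_probes = 10000,
                              n_cases = 8,
                              n_controls = 21,
                              n_signature_probes = 100,
                              effect_size_range = c(0.15, 0.15),
                              noise_sd = 0.3,
                              dirichlet_concentration = c(Neu = 18, CD4T = 3.9,
                                                          CD8T = 2.4, Bcell = 1.8,
                                                          NK = 1.8, Mono = 2.1),
                              age_range = c(3, 15),
                              n_age_effect_probes = 200,
                              age_slope = 0.005,
                              n_sex_effect_probes = 200,
                              sex_effect = 0.05,
                              qc_fail = c(detection = 50, snp = 300,
                                          cross_reactive = 150, extreme_beta = 20,
                                          non_cpg = 60, sex_chromosome = 400),
                              seed = 1) {
  cfg <- list(n_probes = n_probes, n_cases = n_cases, n_controls = n_controls,
              n_signature_probes = n_signature_probes,
              effect_size_range = effect_size_range, noise_sd = noise_sd,
              dirichlet_concentration = dirichlet_concentration,
              age_range = age_range,
              n_age_effect_probes = n_age_effect_probes, age_slope = age_slope,
              n_sex_effect_probes = n_sex_effect_probes, sex_effect = sex_effect,
              qc_fail = qc_fail, seed = seed)
  needed <- c("detection", "snp", "cross_reactive", "extreme_beta",
              "non_cpg", "sex_chromosome")
  .stop_if(!all(needed %in% names(cfg$qc_fail)),
           "qc_fail must name counts for: ", paste(needed, collapse = ", "))
  .stop_if(any(cfg$qc_fail < 0) || cfg$n_signature_probes < 0 ||
             cfg$n_cases < 0 || cfg$n_controls < 0, "counts must be >= 0")
  .stop_if(sum(cfg$qc_fail) > n_probes,
           "sum of planted QC-failing probes exceeds n_probes")
  .stop_if(any(effect_size_range <= 0) || any(effect_size_range >= 1),
           "effect_size_range must lie within (0, 1)")
  .stop_if(cfg$noise_sd < 0, "noise_sd must be >= 0")
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate synthetic cell-type reference methylation profiles
#'
#' Builds mean beta profiles for `n_cell_types` leukocyte populations. Most
#' probes share a common bimodal baseline across cell types (small jitter);
#' a fraction (`frac_discriminating`, default 10%) are cell-type
#' discriminating, with per-type betas spread widely so that the
#' between-type range typically exceeds 0.3 — these are the probes that
#' make reference-based deconvolution identifiable.
#'
#' @param n_cell_types number of cell types (>= 2).
#' @param n_probes number of reference probes.
#' @param seed integer seed.
#' @param frac_discriminating fraction of probes made cell-type specific.
#' @param cell_types optional character names; defaults to six blood
#'   leukocyte labels when `n_cell_types == 6`.
#' @return list of class `cell_type_reference` with `profiles` (probes x
#'   cell types matrix in \[0,1\]) and `discriminating` (logical per probe).
#' @export
make_reference_profiles <- function(n_cell_types = 6, n_probes = 10000,
                                    seed = 1, frac_discriminating = 0.1,
                                    cell_types = NULL) {
  .stop_if(n_cell_types < 2, "need at least 2 cell types")
  if (is.null(cell_types)) {
    cell_types <- if (n_cell_types == 6)
      c("Neu", "CD4T", "CD8T", "Bcell", "NK", "Mono")
    else paste0("cell", seq_len(n_cell_types))
  }
  .stop_if(length(cell_types) != n_cell_types, "cell_types length mismatch")
  set.seed(seed)
  probe_ids <- sprintf("cg%06d", seq_len(n_probes))
  # bimodal baseline typical of array methylation
  base <- stats::rbeta(n_probes, 0.4, 0.4)
  prof <- matrix(rep(base, n_cell_types), n_probes, n_cell_types)
  prof <- prof + matrix(stats::rnorm(n_probes * n_cell_types, 0, 0.005),
                        n_probes, n_cell_types)
  disc <- seq_len(n_probes) %in%
    sample.int(n_probes, round(frac_discriminating * n_probes))
  n_disc <- sum(disc)
  if (n_disc > 0)
    prof[disc, ] <- matrix(stats::runif(n_disc * n_cell_types, 0.05, 0.95),
                           n_disc, n_cell_types)
  prof <- .clip01(prof)
  dimnames(prof) <- list(probe_ids, cell_types)
  structure(list(profiles = prof, discriminating = disc),
            class = "cell_type_reference")
}

# Build probe annotation for the reference probe set and pick the disjoint
# planted QC-failing sets. Islands are runs of consecutive probes; shores are
# probes within 2 kb of an island edge, shelves within the next 2 kb.
.simulate_annotation <- function(probe_ids, qc_fail) {
  n <- length(probe_ids)
  n_sex <- qc_fail[["sex_chromosome"]]
  chrom <- character(n)
  if (n_sex > 0) {
    sex_idx <- (n - n_sex + 1):n  # trailing block plays chrX/chrY
    chrom[sex_idx] <- rep(c("chrX", "chrY"), length.out = n_sex)
  } else sex_idx <- integer(0)
  auto_idx <- setdiff(seq_len(n), sex_idx)
  chrom[auto_idx] <- paste0("chr", rep(1:22, length.out = 22)[
    ceiling(seq_along(auto_idx) / ceiling(length(auto_idx) / 22))])
  position <- integer(n)
  island <- logical(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    position[idx] <- cumsum(sample(200:1800, length(idx), replace = TRUE)) + 10000L
    # island runs of 3-8 consecutive probes covering ~15% of the chromosome
    i <- 1
    while (i <= length(idx)) {
      if (stats::runif(1) < 0.03) {
        len <- sample(3:8, 1)
        island[idx[i:min(i + len - 1, length(idx))]] <- TRUE
        i <- i + len
      } else i <- i + 1
    }
  }
  relation <- rep("OpenSea", n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    isl <- idx[island[idx]]
    if (length(isl) == 0) next
    runs <- split(isl, cumsum(c(1, diff(isl) != 1)))
    starts <- vapply(runs, function(r) position[r[1]], numeric(1))
    ends <- vapply(runs, function(r) position[r[length(r)]], numeric(1))
    for (j in idx) {
      if (island[j]) { relation[j] <- "Island"; next }
      d_up <- starts - position[j]   # >0 when probe is upstream of island
      d_dn <- position[j] - ends
      gaps <- pmax(d_up, d_dn)      # distance to each island interval
      k <- which.min(gaps)
      if (gaps[k] <= 2000) relation[j] <- if (d_up[k] > 0) "N_Shore" else "S_Shore"
      else if (gaps[k] <= 4000) relation[j] <- if (d_up[k] > 0) "N_Shelf" else "S_Shelf"
    }
  }
  # plant the autosomal QC-failing categories on disjoint probe sets
  pool <- sample(auto_idx)
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  sets <- list(detection = take(qc_fail[["detection"]]),
               snp = take(qc_fail[["snp"]]),
               cross_reactive = take(qc_fail[["cross_reactive"]]),
               extreme_beta = take(qc_fail[["extreme_beta"]]),
               non_cpg = take(qc_fail[["non_cpg"]]),
               sex_chromosome = sex_idx)
  probe_class <- rep("cg", n)
  probe_class[sets$non_cpg] <- "ch"
  snp_maf <- rep(NA_real_, n)
  snp_maf[sets$snp] <- stats::runif(length(sets$snp), 0.015, 0.4)
  # a few common probes with MAF <= 1% that must survive the SNP filter
  benign <- pool[seq_len(min(50, floor(length(pool) / 4)))]
  snp_maf[benign] <- stats::runif(length(benign), 0, 0.009)
  cross_reactive <- logical(n)
  cross_reactive[sets$cross_reactive] <- TRUE
  ann <- data.frame(probe_id = probe_ids, chromosome = chrom,
                    position = position, probe_class = probe_class,
                    island_relation = relation, snp_maf = snp_maf,
                    cross_reactive = cross_reactive, stringsAsFactors = FALSE)
  attr(ann, "qc_sets") <- lapply(sets, function(ix) probe_ids[ix])
  attr(ann, "clean_pool") <- probe_ids[pool[!(pool %in% benign)]]
  ann
}

#' Simulate a case/control methylation cohort with known truth
#'
#' Each sample's baseline beta profile is a Dirichlet-weighted mixture of the
#' cell-type reference profiles. Case samples additionally receive the
#' planted signature effect (added on the beta scale, then clipped); linear
#' age trends and additive sex offsets are planted at designated probes;
#' measurement noise is applied on the logit scale so values stay in (0, 1).
#' QC-failing probes are realized per category: high detection p-values,
#' SNP-overlapping MAF > 1%, cross-reactive flags, betas pinned to 0/1 in
#' more than 25% of samples, non-CpG probe class, and chrX/chrY placement.
#'
#' @param config a [simulation_config()].
#' @param reference optional [make_reference_profiles()] output; generated
#'   from `config` when `NULL`.
#' @param annotation optional probe annotation from a previous run (reused so
#'   a validation batch shares the discovery run's probe geography and
#'   planted QC categories).
#' @param signature optional `data.frame(probe_id, delta_beta)` to re-plant
#'   an existing signature (used for validation batches); drawn fresh when
#'   `NULL`.
#' @param cohort cohort label written to the sample sheet.
#' @param prefix sample-id prefix (defaults to the cohort label).
#' @return list with `beta`, `sheet`, `annotation`, `detp`, `truth`
#'   (class `simulation_truth`), and `reference`.
#' @export
simulate_cohort <- function(config, reference = NULL, annotation = NULL,
                            signature = NULL, cohort = "discovery",
                            prefix = cohort) {
  .stop_if(!inherits(config, "simulation_config"), "config must be a simulation_config")
  set.seed(config$seed)
  if (is.null(reference))
    reference <- make_reference_profiles(
      n_cell_types = length(config$dirichlet_concentration),
      n_probes = config$n_probes, seed = config$seed,
      cell_types = names(config$dirichlet_concentration))
  ref <- reference$profiles
  .stop_if(ncol(ref) != length(config$dirichlet_concentration),
           "reference cell types must match dirichlet_concentration length")
  if (is.null(annotation))
    annotation <- .simulate_annotation(rownames(ref), config$qc_fail)
  .stop_if(!all(rownames(ref) %in% annotation$probe_id),
           "reference probes must be a subset of the annotation")
  qc_sets <- attr(annotation, "qc_sets")
  clean_pool <- attr(annotation, "clean_pool")
  .stop_if(is.null(qc_sets) || is.null(clean_pool),
           "annotation must carry planted qc_sets (use a simulated annotation)")

  n_samp <- config$n_cases + config$n_controls
  ids <- c(sprintf("%s_case_%03d", prefix, seq_len(config$n_cases)),
           sprintf("%s_ctrl_%03d", prefix, seq_len(config$n_controls)))
  group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  sheet <- data.frame(
    sample_id = ids, group = group,
    age = round(stats::runif(n_samp, config$age_range[1], config$age_range[2]), 1),
    sex = rep_len(c("M", "F"), n_samp),
    tissue = "blood", cohort = cohort, stringsAsFactors = FALSE)

  W <- .rdirichlet(n_samp, config$dirichlet_concentration)
  dimnames(W) <- list(ids, colnames(ref))
  beta <- ref %*% t(W)

  # planted case/control signature (beta scale)
  if (is.null(signature)) {
    .stop_if(length(clean_pool) < config$n_signature_probes,
             "not enough clean probes to plant the signature; increase ",
             "n_probes or reduce qc_fail counts")
    picked <- sample(clean_pool, config$n_signature_probes)
    delta <- stats::runif(config$n_signature_probes,
                          config$effect_size_range[1],
                          config$effect_size_range[2]) *
      sample(c(-1, 1), config$n_signature_probes, replace = TRUE)
    signature <- data.frame(probe_id = picked, delta_beta = delta,
                            stringsAsFactors = FALSE)
  }
  signature$direction <- ifelse(signature$delta_beta >= 0, "hyper", "hypo")
  is_case <- group == "case"
  if (nrow(signature) > 0 && any(is_case))
    beta[signature$probe_id, is_case] <-
      beta[signature$probe_id, is_case] + signature$delta_beta

  # linear age trends and sex offsets at designated clean probes
  remaining <- setdiff(clean_pool, signature$probe_id)
  age_ids <- if (config$n_age_effect_probes > 0)
    sample(remaining, min(config$n_age_effect_probes, length(remaining))) else character(0)
  remaining <- setdiff(remaining, age_ids)
  sex_ids <- if (config$n_sex_effect_probes > 0)
    sample(remaining, min(config$n_sex_effect_probes, length(remaining))) else character(0)
  if (length(age_ids) > 0) {
    slope <- config$age_slope * sample(c(-1, 1), length(age_ids), replace = TRUE)
    beta[age_ids, ] <- beta[age_ids, ] +
      outer(slope, sheet$age - mean(config$age_range))
  } else slope <- numeric(0)
  if (length(sex_ids) > 0) {
    sx <- config$sex_effect * sample(c(-1, 1), length(sex_ids), replace = TRUE)
    male <- sheet$sex == "M"
    if (any(male)) beta[sex_ids, male] <- beta[sex_ids, male] + sx
  } else sx <- numeric(0)

  clipped <- sum(beta < 0 | beta > 1)
  beta <- .clip01(beta)
  if (config$noise_sd > 0)
    beta <- stats::plogis(stats::qlogis(.squeeze(beta)) +
                            matrix(stats::rnorm(length(beta), 0, config$noise_sd),
                                   nrow(beta), ncol(beta)))

  # realize the extreme-beta failures: pinned to 0/1 in >25% of samples
  for (pid in qc_sets$extreme_beta) {
    hit <- sample.int(n_samp, ceiling(0.3 * n_samp))
    beta[pid, hit] <- sample(c(0, 1), 1)
  }

  detp <- matrix(stats::runif(length(beta), 0, 0.005), nrow(beta), ncol(beta),
                 dimnames = dimnames(beta))
  for (pid in qc_sets$detection) {
    hit <- sample.int(n_samp, ceiling(0.5 * n_samp))
    detp[pid, hit] <- stats::runif(length(hit), 0.02, 0.6)
  }

  truth <- structure(list(signature = signature, proportions = W,
                          qc = qc_sets, age_probes = data.frame(
                            probe_id = age_ids, slope = slope,
                            stringsAsFactors = FALSE),
                          sex_probes = data.frame(probe_id = sex_ids,
                                                  effect = sx,
                                                  stringsAsFactors = FALSE),
                          clipped = clipped),
                     class = "simulation_truth")
  list(beta = beta, sheet = sheet, annotation = annotation, detp = detp,
       truth = truth, reference = reference)
}

#' Simulate a gene annotation aligned to a probe annotation
#'
#' Places genes on the same chromosomes as the probes so that window-based
#' CpG-to-gene mapping and category enrichment can run end to end on
#' synthetic data. Roughly half the genes are anchored near a random probe
#' (so they receive CpG hits); the rest are placed in intergenic space.
#'
#' @param ann probe annotation `data.frame`.
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @param width_range gene length range in bp.
#' @return gene annotation `data.frame(gene, chromosome, start, end)`.
#' @export
simulate_gene_annotation <- function(ann, n_genes = 250, seed = 1,
                                     width_range = c(2000, 50000)) {
  set.seed(seed)
  anchors <- ann[sample.int(nrow(ann), n_genes, replace = TRUE), ]
  width <- sample(width_range[1]:width_range[2], n_genes, replace = TRUE)
  near <- stats::runif(n_genes) < 0.5
  start <- ifelse(near,
                  pmax(1, anchors$position - sample(0:5000, n_genes, replace = TRUE)),
                  anchors$position + 60000L)
  data.frame(gene = sprintf("GENE%04d", seq_len(n_genes)),
             chromosome = anchors$chromosome,
             start = as.integer(start), end = as.integer(start + width),
             stringsAsFactors = FALSE)
}
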