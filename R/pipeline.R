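#' Default end-to-end pipeline configuration
#'
#' Nested configuration for [run_discovery_pipeline()]: the simulation
#' design (a [simulation_config()]), QC thresholds, deconvolution probe
#' count, signature thresholds, classifier settings, and the validation /
#' specificity batch sizes. Every stage seed is derived deterministically
#' from the single top-level `seed`.
#'
#' @param seed integer master seed.
#' @param ... overrides for the top-level entries (`simulate`, `qc`,
#'   `deconv_probes`, `alpha`, `delta`, `classifier`,
#'   `n_validation_cases`, `n_validation_controls`, `n_other_syndrome`).
#' @return list of class `episig_config`.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    simulate = simulation_config(seed = seed),
    qc = qc_params(),
    deconv_probes = 200,
    alpha = 0.05,
    delta = 0.10,
    classifier = list(kernel = "linear", cost = 1),
    n_validation_cases = 8,
    n_validation_controls = 200,
    n_other_syndrome = 20)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "episig_config"
  cfg
}

#' Run the full discovery-to-classification pipeline on synthetic data
#'
#' Stages, in order: (1) simulate a discovery cohort with known truth;
#' (2) probe QC cascade; (3) reference-based cell-type deconvolution;
#' (4) covariate-adjusted moderated differential methylation and
#' dual-threshold signature selection; (5) train the SVM probability
#' classifier at the signature probes; (6) simulate and score a fresh
#' validation batch carrying the same planted signature, plus an
#' "other syndrome" specificity cohort whose planted signature is disjoint
#' from the model's probes; (7) island/shore enrichment and gene mapping of
#' the signature. Any stage failure halts the run with the stage named.
#'
#' When `out_dir` is given, each stage's outputs are written (as the
#' package's tab-delimited formats and JSON) before the next stage begins,
#' and a run manifest with per-file MD5 digests is stored; identical config
#' and seed reproduce identical digests.
#'
#' @param config an [default_config()] object.
#' @param out_dir optional output directory.
#' @return list with all stage results (`discovery`, `qc`, `proportions`,
#'   `dm`, `signature`, `model`, `validation_scores`, `panel`,
#'   `enrichment`, `gene_map`, `manifest`).
#' @export
run_discovery_pipeline <- function(config = default_config(), out_dir = NULL) {
  .stop_if(!inherits(config, "episig_config"), "config must be an episig_config")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(writer, obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(obj, path)
    written <<- c(written, path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # 1. simulate discovery cohort
  disc <- stage("simulate", simulate_cohort(config$simulate, cohort = "discovery"))
  emit(write_beta_matrix, disc$beta, "discovery_beta.tsv")
  emit(write_sample_sheet, disc$sheet, "discovery_sheet.tsv")
  emit(write_probe_annotation, disc$annotation, "probe_annotation.tsv")
  emit(write_detection_p, disc$detp, "discovery_detp.tsv")

  # 2. probe QC cascade
  qc <- stage("qc", filter_probes(disc$beta, disc$detp, disc$annotation, config$qc))
  emit(function(obj, path) .write_table(qc_summary_table(obj), path),
       qc$report, "qc_report.tsv")

  # 3. cell-type deconvolution
  probes_deconv <- stage("deconv", intersect(
    select_discriminating_probes(disc$reference,
                                 min(config$deconv_probes,
                                     nrow(disc$reference$profiles))),
    rownames(qc$beta)))
  props <- stage("deconv", estimate_proportions(qc$beta, disc$reference,
                                                probes_deconv))
  emit(function(obj, path) .write_table(
    data.frame(sample_id = rownames(obj), obj, check.names = FALSE), path),
    props, "cell_proportions.tsv")

  # 4. differential methylation + signature selection
  dm <- stage("dmp", dm_analysis(qc$beta, disc$sheet, props))
  sig <- stage("dmp", select_signature(dm, config$alpha, config$delta))
  emit(function(obj, path) .write_table(obj, path), dm, "dm_results.tsv")
  emit(write_signature, sig, "signature.tsv")
  .stop_if(nrow(sig) == 0, "pipeline stage 'dmp' selected an empty signature")

  # 5. train classifier
  model <- stage("classify", train_classifier(
    qc$beta, disc$sheet$group, sig$probe_id, config$classifier,
    seed = config$seed))
  emit(save_model, model, "model.json")

  # 6. fresh validation batch (same reference/annotation/planted signature)
  val_cfg <- config$simulate
  val_cfg$n_cases <- config$n_validation_cases
  val_cfg$n_controls <- config$n_validation_controls
  val_cfg$seed <- config$seed + 1000L
  val <- stage("validate", simulate_cohort(
    val_cfg, reference = disc$reference, annotation = disc$annotation,
    signature = disc$truth$signature, cohort = "validation"))
  val_scores <- stage("validate", score_samples(model, val$beta))
  val_scores$group <- val$sheet$group
  emit(function(obj, path) .write_table(obj, path), val_scores,
       "validation_scores.tsv")

  # other-syndrome specificity cohort: planted signature disjoint from model
  other_cfg <- config$simulate
  other_cfg$n_cases <- config$n_other_syndrome
  other_cfg$n_controls <- 0
  other_cfg$seed <- config$seed + 2000L
  clean <- attr(disc$annotation, "clean_pool")
  other_pool <- setdiff(clean, disc$truth$signature$probe_id)
  set.seed(config$seed + 3000L)
  other_sig <- data.frame(
    probe_id = sample(other_pool, nrow(disc$truth$signature)),
    delta_beta = disc$truth$signature$delta_beta, stringsAsFactors = FALSE)
  other <- stage("panel", simulate_cohort(
    other_cfg, reference = disc$reference, annotation = disc$annotation,
    signature = other_sig, cohort = "classification", prefix = "other"))
  panel <- stage("panel", specificity_panel(model, list(
    other_syndrome = other$beta,
    validation_controls = val$beta[, val$sheet$group == "control", drop = FALSE])))
  emit(function(obj, path) .write_table(obj, path), panel, "specificity_panel.tsv")

  # 7. enrichment and gene mapping
  enr <- stage("annotate", island_shore_enrichment(
    sig, disc$annotation, rownames(qc$beta)))
  genes <- stage("annotate", simulate_gene_annotation(
    disc$annotation, seed = config$seed))
  gene_map <- stage("annotate", map_genes(sig, disc$annotation, genes))
  emit(function(obj, path) .write_table(obj, path), enr, "island_shore_enrichment.tsv")
  emit(function(obj, path) .write_table(obj, path), gene_map, "signature_genes.tsv")

  manifest <- list(
    config_hash = .hash_config(config),
    seed = config$seed,
    version = as.character(utils::packageVersion("episig")),
    stages = c("simulate", "qc", "deconv", "dmp", "classify", "validate",
               "panel", "annotate"),
    files = if (length(written) > 0)
      as.list(tools::md5sum(written)) else list())
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)

  list(discovery = disc, qc = qc, proportions = props, dm = dm,
       signature = sig, model = model, validation = val,
       validation_scores = val_scores, panel = panel, enrichment = enr,
       gene_map = gene_map, manifest = manifest)
}

.hash_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Score a single sample against a trained model
#'
#' Scores one sample (e.g. a variant of uncertain significance) and places
#' its score in the context of the model's training distribution: the
#' percentile among training control scores and among training case scores.
#'
#' @param model an `episig_model` (with training scores, as produced by
#'   [train_classifier()]).
#' @param sample_beta one-column beta matrix (or a named numeric vector of
#'   betas) covering all model probes.
#' @return one-row `data.frame(sample_id, score, label,
#'   control_percentile, case_percentile)`.
#' @export
classify_case <- function(model, sample_beta) {
  if (is.null(dim(sample_beta)))
    sample_beta <- matrix(sample_beta, ncol = 1,
                          dimnames = list(names(sample_beta), "sample"))
  .stop_if(ncol(sample_beta) != 1, "classify_case scores a single sample")
  sc <- score_samples(model, sample_beta)
  ctrl <- model$training_scores[model$training_labels == "control"]
  cas <- model$training_scores[model$training_labels == "case"]
  sc$control_percentile <- 100 * mean(ctrl <= sc$score)
  sc$case_percentile <- 100 * mean(cas <= sc$score)
  sc
}
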