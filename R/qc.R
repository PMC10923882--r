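#' QC thresholds for the probe-removal cascade
#'
#' @param detp_thresh detection p-value above which a measurement is a
#'   detection failure (platform convention 0.01).
#' @param detp_frac fraction of samples that may fail detection before the
#'   probe is removed (default 0.05, i.e. removed when > 5% of samples fail).
#' @param maf_thresh minor-allele-frequency cutoff; probes overlapping a SNP
#'   with MAF above 1% are removed.
#' @param extreme_frac probes with raw beta exactly 0 or 1 in more than this
#'   fraction of samples (default 25%) are removed.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(detp_thresh = 0.01, detp_frac = 0.05,
                      maf_thresh = 0.01, extreme_frac = 0.25) {
  structure(list(detp_thresh = detp_thresh, detp_frac = detp_frac,
                 maf_thresh = maf_thresh, extreme_frac = extreme_frac),
            class = "qc_params")
}

.QC_CATEGORIES <- c("detection", "snp", "cross_reactive", "extreme_beta",
                    "non_cpg", "sex_chromosome")

#' Probe-removal cascade
#'
#' Applies the six removal categories in a fixed order: (1) detection
#' failures (detection p > `detp_thresh` in more than `detp_frac` of
#' samples, or any missing beta value), (2) SNP-overlapping probes with
#' MAF > `maf_thresh`, (3) cross-reactive probes, (4) probes with beta
#' exactly 0 or 1 in more than `extreme_frac` of samples, (5) non-CpG
#' probes (class != cg), (6) chrX/chrY probes. Accounting is sequential
#' first-hit: a probe is counted once, under the first category that removes
#' it, so the per-category counts always sum to `n_input - n_remaining`.
#'
#' @param beta beta matrix (probes x samples); missing values allowed.
#' @param detp detection p-value matrix with identical axes.
#' @param ann probe annotation covering every probe in `beta`.
#' @param params a [qc_params()].
#' @return list with `beta` (filtered, complete matrix) and `report`
#'   (class `filter_report`).
#' @export
filter_probes <- function(beta, detp, ann, params = qc_params()) {
  validate_beta_matrix(beta, allow_missing = TRUE)
  .check_paired_axes(beta, detp)
  unann <- setdiff(rownames(beta), ann$probe_id)
  .stop_if(length(unann) > 0, "unannotated probe(s): ",
           paste(utils::head(unann, 5), collapse = ", "))
  a <- ann[match(rownames(beta), ann$probe_id), ]
  n_samp <- ncol(beta)

  fails <- list(
    detection = rowMeans(detp > params$detp_thresh) > params$detp_frac |
      rowSums(is.na(beta)) > 0,
    snp = !is.na(a$snp_maf) & a$snp_maf > params$maf_thresh,
    cross_reactive = a$cross_reactive,
    extreme_beta = rowMeans(beta == 0 | beta == 1, na.rm = TRUE) > params$extreme_frac,
    non_cpg = a$probe_class != "cg",
    sex_chromosome = a$chromosome %in% c("chrX", "chrY")
  )
  removed_so_far <- rep(FALSE, nrow(beta))
  lists <- counts <- stats::setNames(vector("list", length(.QC_CATEGORIES)),
                                     .QC_CATEGORIES)
  for (cat in .QC_CATEGORIES) {
    hit <- fails[[cat]] & !removed_so_far
    lists[[cat]] <- rownames(beta)[hit]
    counts[[cat]] <- sum(hit)
    removed_so_far <- removed_so_far | hit
  }
  report <- structure(list(
    counts = unlist(counts), probes = lists,
    n_input = nrow(beta), n_remaining = sum(!removed_so_far),
    params = params), class = "filter_report")
  filtered <- beta[!removed_so_far, , drop = FALSE]
  validate_beta_matrix(filtered, allow_missing = FALSE)
  list(beta = filtered, report = report)
}

#' Human-readable QC summary
#'
#' @param report a `filter_report` from [filter_probes()].
#' @return a `data.frame` with one row per removal category (sequential
#'   first-hit accounting) plus input/remaining totals.
#' @export
qc_summary_table <- function(report) {
  .stop_if(!inherits(report, "filter_report"), "need a filter_report")
  data.frame(
    category = c("input", .QC_CATEGORIES, "remaining"),
    n = c(report$n_input, unname(report$counts), report$n_remaining),
    stringsAsFactors = FALSE)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Probe QC cascade (sequential first-hit accounting)\n")
  print(qc_summary_table(x), row.names = FALSE)
  invisible(x)
}
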