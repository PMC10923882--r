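#' Build the covariate-adjusted design matrix
#'
#' Columns, in fixed order: intercept, group indicator (case = 1,
#' control = 0), age in years, sex indicator (M = 1, F = 0), and the
#' estimated cell-type proportions with one reference type dropped (the
#' proportions sum to one, so keeping all of them would make the design
#' collinear with the intercept). Constant covariate columns (other than
#' the intercept) are dropped with a warning; the result is rank-checked.
#'
#' @param records sample sheet rows for the modeled samples; `group` must be
#'   case/control only.
#' @param props optional samples x cell-types proportion matrix
#'   (rows matching `records$sample_id`).
#' @param drop_cell_type name of the cell type to drop; defaults to the
#'   first column of `props`.
#' @return numeric design matrix (samples x columns) with rownames =
#'   sample ids.
#' @export
build_design <- function(records, props = NULL, drop_cell_type = NULL) {
  bad <- setdiff(unique(records$group), c("case", "control"))
  .stop_if(length(bad) > 0, "unknown group in design: ", paste(bad, collapse = ", "))
  X <- cbind(intercept = 1,
             group = as.numeric(records$group == "case"),
             age = records$age,
             sexM = as.numeric(records$sex == "M"))
  if (!is.null(props)) {
    .stop_if(!all(records$sample_id %in% rownames(props)),
             "proportions missing for some samples")
    P <- props[records$sample_id, , drop = FALSE]
    if (is.null(drop_cell_type)) drop_cell_type <- colnames(P)[1]
    .stop_if(!drop_cell_type %in% colnames(P),
             "drop_cell_type not a proportion column")
    X <- cbind(X, P[, setdiff(colnames(P), drop_cell_type), drop = FALSE])
  }
  rownames(X) <- records$sample_id
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) stats::var(v) > 0))
  if (!all(keep)) {
    warning("dropping constant design column(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  .stop_if(qr(X)$rank < ncol(X), "design matrix is rank-deficient")
  .stop_if(!"group" %in% colnames(X), "group column missing from design")
  X
}

#' Per-probe ordinary least squares via a shared QR decomposition
#'
#' Fits every probe's linear model against the same design in one QR
#' factorization. Returns the group coefficient, its standard error, the
#' residual variance s^2 (beta^2 units), the residual degrees of freedom
#' d = n - p (identical across probes), and the unscaled standard deviation
#' of the group coefficient (SE / s), which is what variance moderation
#' rescales.
#'
#' @param beta complete beta matrix (probes x samples).
#' @param design design matrix from [build_design()]; rows must align with
#'   the beta columns.
#' @return `data.frame` with columns `probe_id`, `coef`, `se`, `s2`, `df`,
#'   `stdev_unscaled`.
#' @export
fit_linear_models <- function(beta, design) {
  validate_beta_matrix(beta, allow_missing = FALSE)
  .stop_if(!identical(colnames(beta), rownames(design)),
           "design rows must align with beta samples")
  n <- ncol(beta); p <- ncol(design)
  .stop_if(n <= p, "need more samples than design columns (n > p)")
  QR <- qr(design)
  Y <- t(beta)                              # samples x probes
  coefs <- qr.coef(QR, Y)                   # p x probes
  res <- Y - design %*% coefs
  d <- n - p
  s2 <- colSums(res^2) / d
  xtx_inv <- chol2inv(qr.R(QR))
  cg <- which(colnames(design) == "group")
  unscaled <- sqrt(xtx_inv[cg, cg])
  data.frame(probe_id = rownames(beta),
             coef = coefs[cg, ],
             se = sqrt(s2) * unscaled,
             s2 = s2, df = d,
             stdev_unscaled = unscaled,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Invert the trigamma function by Newton iteration; used by the
# method-of-moments prior fit.
.trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(NA_real_)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Shrinks each probe's residual variance toward a pooled prior estimated
#' from all probes, then forms moderated t-statistics. The prior
#' (d0 degrees of freedom, s0^2 scale) is fit by method of moments on
#' log s^2: with z = log s^2 and e = z - digamma(d/2) + log(d/2), the excess
#' of var(e) over trigamma(d/2) identifies trigamma(d0/2), inverted by
#' Newton iteration, and mean(e) then identifies s0^2. The posterior
#' variance is s~^2 = (d0 s0^2 + d s^2) / (d0 + d), the moderated t is
#' coef / (stdev_unscaled * s~), and two-sided p-values use d0 + d degrees
#' of freedom. When the moment estimate of the excess is non-positive the
#' prior is degenerate (d0 = Inf; every probe gets s0^2 = mean(s^2), so
#' identical observed variances moderate to themselves); if the inversion
#' fails the fit falls back to no moderation (d0 = 0, ordinary t) with a
#' warning. Exactly-zero variances are offset to 1e-5 of the median before
#' the log-moment fit.
#'
#' @param fits output of [fit_linear_models()].
#' @param prior_df optional fixed prior degrees of freedom overriding the
#'   empirical fit: `0` gives ordinary (unmoderated) t-statistics, `Inf`
#'   pools every probe fully to the mean variance.
#' @return `data.frame` with `probe_id`, `coef`, `t`, `p`, `p_adj`
#'   (Benjamini-Hochberg), plus attributes `d0` and `s0_2`.
#' @export
moderate <- function(fits, prior_df = NULL) {
  .stop_if(sum(fits$s2 > 0) < 2, "need at least 2 probes with positive s2")
  d <- fits$df[1]
  m <- stats::median(fits$s2)
  s2 <- pmax(fits$s2, 1e-5 * m)
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (!is.null(prior_df)) {
    d0 <- prior_df
    s0_2 <- if (is.infinite(d0)) mean(s2)
    else if (d0 == 0) NA_real_
    else exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else if (is.finite(evar) && evar > 0) {
    half_d0 <- .trigamma_inverse(evar)
    if (is.na(half_d0)) {
      warning("trigamma inversion failed; falling back to no moderation (d0 = 0)",
              call. = FALSE)
      d0 <- 0; s0_2 <- NA_real_
    } else {
      d0 <- 2 * half_d0
      s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    d0 <- Inf
    s0_2 <- mean(s2)
  }
  s2_post <- if (d0 == 0) s2
  else if (is.infinite(d0)) rep(s0_2, nrow(fits))
  else (d0 * s0_2 + d * s2) / (d0 + d)
  tstat <- fits$coef / (fits$stdev_unscaled * sqrt(s2_post))
  # total df capped at the pooled residual df, so an infinite prior yields
  # a finite (if large) reference distribution
  df_total <- min(d0 + d, nrow(fits) * d)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(probe_id = fits$probe_id, coef = fits$coef,
                    t = tstat, p = p, p_adj = adjust_bh(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper over the standard step-up FDR adjustment; input order
#' is preserved and adjusted values are monotone and capped at 1.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(p) {
  .stop_if(any(is.na(p)) || any(p < 0 | p > 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-probe difference in group mean methylation
#'
#' Delta beta is mean(case) - mean(control) of the raw betas, per probe —
#' deliberately unadjusted for covariates, since it is an effect size on
#' the methylation-fraction scale.
#'
#' @param beta beta matrix.
#' @param groups character vector aligned with the beta columns
#'   ("case"/"control").
#' @return named numeric vector of delta beta per probe.
#' @export
delta_beta <- function(beta, groups) {
  .stop_if(length(groups) != ncol(beta), "groups must align with beta samples")
  .stop_if(!any(groups == "case") || !any(groups == "control"),
           "both groups must be non-empty")
  rowMeans(beta[, groups == "case", drop = FALSE]) -
    rowMeans(beta[, groups == "control", drop = FALSE])
}

#' Select the episignature by dual thresholds
#'
#' Keeps probes with BH-adjusted p < `alpha` and |delta beta| > `delta`
#' (both strict), sorted by adjusted p, then |delta beta| descending, then
#' probe id. An empty signature is a valid, serializable result.
#'
#' @param results moderated results with columns `probe_id`, `p_adj`, and
#'   `delta_beta`.
#' @param alpha FDR threshold (default 0.05).
#' @param delta minimum |delta beta| (default 0.10, i.e. a 10% methylation
#'   difference).
#' @return `data.frame` of class `signature` with columns `probe_id`,
#'   `delta_beta`, `direction` (hyper/hypo), `p_adj`.
#' @export
select_signature <- function(results, alpha = 0.05, delta = 0.10) {
  .stop_if(!all(c("probe_id", "p_adj", "delta_beta") %in% names(results)),
           "results need probe_id, p_adj and delta_beta columns")
  keep <- results$p_adj < alpha & abs(results$delta_beta) > delta
  sig <- results[keep, c("probe_id", "delta_beta", "p_adj"), drop = FALSE]
  sig$direction <- ifelse(sig$delta_beta >= 0, "hyper", "hypo")
  sig <- sig[order(sig$p_adj, -abs(sig$delta_beta), sig$probe_id),
             c("probe_id", "delta_beta", "direction", "p_adj")]
  rownames(sig) <- NULL
  attr(sig, "alpha") <- alpha
  attr(sig, "delta") <- delta
  class(sig) <- c("signature", "data.frame")
  sig
}

#' Variance pre-filter for cross-tissue analysis
#'
#' Keeps probes whose beta range across all samples exceeds `min_range`
#' (default 10%), reducing the multiple-testing burden before differential
#' analysis in a second tissue. Standard deviation is available as an
#' alternative statistic.
#'
#' @param beta complete beta matrix.
#' @param min_range variability threshold (beta units).
#' @param stat `"range"` (default) or `"sd"`.
#' @return list with `beta` (kept probes) and `removed` (count).
#' @export
variance_filter <- function(beta, min_range = 0.10, stat = c("range", "sd")) {
  stat <- match.arg(stat)
  v <- if (stat == "range")
    apply(beta, 1, function(x) max(x) - min(x))
  else apply(beta, 1, stats::sd)
  keep <- v > min_range
  list(beta = beta[keep, , drop = FALSE], removed = sum(!keep))
}

#' Full differential-methylation analysis for one cohort
#'
#' Convenience composition: builds the design, fits per-probe models,
#' moderates the variances, and appends the raw group-mean delta beta.
#'
#' @inheritParams build_design
#' @param beta complete beta matrix restricted to the modeled samples.
#' @return moderated result table with a `delta_beta` column.
#' @export
dm_analysis <- function(beta, records, props = NULL, drop_cell_type = NULL) {
  .stop_if(!identical(colnames(beta), records$sample_id),
           "beta samples must align with records")
  design <- build_design(records, props, drop_cell_type)
  fits <- fit_linear_models(beta, design)
  res <- moderate(fits)
  res$delta_beta <- unname(delta_beta(beta, records$group))
  res
}

#' Write / read a signature table
#' @param sig a `signature` object.
#' @param path file path.
#' @param dialect `"tab"` or `"comma"`.
#' @export
write_signature <- function(sig, path, dialect = "tab") {
  .write_table(as.data.frame(sig), path, dialect)
}

#' @rdname write_signature
#' @export
read_signature <- function(path, dialect = "tab") {
  df <- .read_table(path, dialect)
  class(df) <- c("signature", "data.frame")
  df
}
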