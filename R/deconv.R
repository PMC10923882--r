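#' Select cell-type discriminating probes from a reference
#'
#' Ranks reference probes by their between-cell-type beta range (max - min
#' across cell types) and returns the top `k` probe ids; ties are broken by
#' probe id order.
#'
#' @param reference a [make_reference_profiles()] object (or any list with a
#'   `profiles` probes x cell-types matrix).
#' @param k number of probes to select.
#' @return character vector of `k` probe ids.
#' @export
select_discriminating_probes <- function(reference, k) {
  prof <- reference$profiles
  .stop_if(k <= 0, "k must be positive")
  .stop_if(k > nrow(prof), "k exceeds the number of reference probes")
  rng <- apply(prof, 1, function(x) max(x) - min(x))
  ord <- order(-rng, rownames(prof))
  rownames(prof)[ord[seq_len(k)]]
}

#' Reference-based cell-type proportion estimation
#'
#' For each sample, solves the constrained least-squares problem
#' min ||R w - b||^2 subject to w >= 0 and sum(w) = 1, where R holds the
#' reference mean-beta profiles at the selected probes and b the sample's
#' betas. The sum-to-one constraint is imposed via an augmentation row of
#' weight 1000 on a non-negative least-squares solve, followed by exact
#' renormalization; the estimator is deterministic.
#'
#' @param beta beta matrix containing at least the selected probes.
#' @param reference a [make_reference_profiles()] object.
#' @param probes probe ids to use; defaults to the 200 most discriminating
#'   (or all reference probes if fewer).
#' @return samples x cell-types matrix of proportions; rows on the simplex.
#' @export
estimate_proportions <- function(beta, reference, probes = NULL) {
  prof <- reference$profiles
  if (is.null(probes))
    probes <- select_discriminating_probes(reference, min(200, nrow(prof)))
  missing_p <- setdiff(probes, rownames(beta))
  .stop_if(length(missing_p) > 0, "probes absent from beta matrix: ",
           paste(utils::head(missing_p, 5), collapse = ", "))
  missing_r <- setdiff(probes, rownames(prof))
  .stop_if(length(missing_r) > 0, "probes absent from reference: ",
           paste(utils::head(missing_r, 5), collapse = ", "))
  .stop_if(length(probes) < ncol(prof),
           "need at least as many probes as cell types")
  R <- prof[probes, , drop = FALSE]
  .stop_if(qr(R)$rank < ncol(R), "reference is rank-deficient after probe selection")
  aug <- 1e3
  A <- rbind(R, rep(aug, ncol(R)))
  W <- t(vapply(colnames(beta), function(s) {
    w <- pracma::lsqnonneg(A, c(beta[probes, s], aug))$x
    w / sum(w)
  }, numeric(ncol(R))))
  dimnames(W) <- list(colnames(beta), colnames(R))
  stopifnot(all(W >= 0), all(abs(rowSums(W) - 1) < 1e-6))
  W
}
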