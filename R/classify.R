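#' Train an SVM probability classifier on signature probes
#'
#' Features are the beta values at the signature probes, standardized by the
#' training mean and SD. A support vector machine (linear kernel by default,
#' cost 1) is fit, and a sigmoid (Platt) calibration maps decision values to
#' scores in \[0, 1\], where the score is the probability of the "case"
#' class. The calibration is fit on held-out decision values from an
#' internal stratified 3-fold cross-validation whose folds are drawn from
#' `seed`, so training is fully deterministic. The fitted model is reduced
#' to a plain serializable form (feature order, scaling constants,
#' weights/support vectors, sigmoid coefficients) and scoring from that
#' form is verified against the underlying fit at train time, so a saved
#' and reloaded model scores bitwise identically. If either class has fewer
#' than 3 members the cross-validated calibration is replaced by a sigmoid
#' fit on the training decision values, with a warning.
#'
#' @param beta beta matrix restricted to (at least) the signature probes.
#' @param labels character vector aligned with beta columns
#'   ("case"/"control").
#' @param signature_probes feature probes, in model feature order; defaults
#'   to all rows of `beta`.
#' @param params list with `kernel` ("linear" or "radial") and `cost`.
#' @param seed integer seed for the internal calibration folds.
#' @return list of class `episig_model`.
#' @export
train_classifier <- function(beta, labels, signature_probes = rownames(beta),
                             params = list(kernel = "linear", cost = 1),
                             seed = 1) {
  .stop_if(length(labels) != ncol(beta), "labels must align with beta samples")
  .stop_if(!all(labels %in% c("case", "control")), "labels must be case/control")
  .stop_if(!all(c("case", "control") %in% labels), "both classes must be present")
  missing_p <- setdiff(signature_probes, rownames(beta))
  .stop_if(length(missing_p) > 0, "signature probe(s) missing from beta: ",
           paste(utils::head(missing_p, 5), collapse = ", "))
  x <- t(beta[signature_probes, , drop = FALSE])
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- scale(x, center = center, scale = scale_)
  y <- factor(labels, levels = c("case", "control"))
  small_class <- min(table(y)) < 3
  kernel <- params$kernel %||% "linear"
  cost <- params$cost %||% 1

  fit <- e1071::svm(xs, y, kernel = kernel, cost = cost, scale = FALSE)
  if (small_class) {
    warning("a class has < 3 members; calibrating sigmoid on training ",
            "decision values", call. = FALSE)
    dec_cal <- .svm_decision(fit, xs)
  } else {
    # held-out decision values from a stratified 3-fold internal CV
    set.seed(seed)
    fold <- integer(length(y))
    for (cl in levels(y)) {
      ix <- which(y == cl)
      fold[ix] <- sample(rep_len(1:3, length(ix)))
    }
    dec_cal <- numeric(length(y))
    for (f in 1:3) {
      sub <- e1071::svm(xs[fold != f, , drop = FALSE],
                        droplevels(y[fold != f]),
                        kernel = kernel, cost = cost, scale = FALSE)
      dec_cal[fold == f] <- .svm_decision(sub, xs[fold == f, , drop = FALSE])
    }
  }
  ab <- .platt_fit(dec_cal, y == "case")
  # serialize with case-positive orientation
  flip <- if (fit$labels[1] == which(fit$levels == "case")) 1 else -1
  model <- structure(list(
    features = signature_probes,
    center = unname(center), scale = unname(scale_),
    kernel = kernel, cost = cost, gamma = fit$gamma,
    w = if (kernel == "linear")
      flip * as.numeric(t(fit$coefs) %*% fit$SV) else NULL,
    sv = if (kernel != "linear") unclass(fit$SV) else NULL,
    coefs = if (kernel != "linear") flip * as.numeric(fit$coefs) else NULL,
    rho = flip * fit$rho,
    probA = unname(ab[1]), probB = unname(ab[2]),
    n_case = sum(y == "case"), n_control = sum(y == "control"),
    seed = seed), class = "episig_model")

  # self-check: the serialized form reproduces the fitted decision values
  dec_chk <- .model_decision(model, xs)
  stopifnot(max(abs(dec_chk - .svm_decision(fit, xs))) < 1e-8)
  sc <- .model_scores(model, xs, standardized = TRUE)
  model$training_scores <- stats::setNames(as.numeric(sc), colnames(beta))
  model$training_labels <- labels
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# decision values normalized so "case" is the positive side, regardless of
# which class libsvm happened to see first
.svm_decision <- function(fit, xs) {
  dv <- attr(stats::predict(fit, xs, decision.values = TRUE),
             "decision.values")
  sgn <- if (grepl("^case/", colnames(dv)[1])) 1 else -1
  sgn * as.numeric(dv)
}

# sigmoid calibration: logistic fit of class on decision value, returned in
# the P(first level) = 1/(1+exp(A*dec+B)) parametrization
.platt_fit <- function(dec, is_case) {
  g <- suppressWarnings(stats::glm(is_case ~ dec, family = stats::binomial()))
  # P(case) = plogis(b0 + b1*dec) = 1/(1+exp(-(b0+b1*dec)))
  c(A = -unname(stats::coef(g)[2]), B = -unname(stats::coef(g)[1]))
}

# case-positive decision values from the serialized model form
.model_decision <- function(model, xs) {
  if (model$kernel == "linear") {
    as.numeric(xs %*% model$w) - model$rho
  } else {
    K <- exp(-model$gamma * outer(rowSums(xs^2), rowSums(model$sv^2), "+") +
               2 * model$gamma * tcrossprod(xs, model$sv))
    as.numeric(K %*% model$coefs) - model$rho
  }
}

# score = P(case) computed from the serialized model form
.model_scores <- function(model, x, standardized = FALSE) {
  if (!standardized)
    x <- scale(x, center = model$center, scale = model$scale)
  1 / (1 + exp(model$probA * .model_decision(model, x) + model$probB))
}

#' Score samples with a trained episignature model
#'
#' Deterministic: the score is the calibrated probability of the "case"
#' class in \[0, 1\]. Labels follow the 0.5 rule — "KdVS-like" above 0.5,
#' "control-like" below, "indeterminate" at exactly 0.5. Probes required by
#' the model but absent from the matrix raise an error (no silent
#' imputation).
#'
#' @param model an `episig_model`.
#' @param beta beta matrix containing all model probes.
#' @return `data.frame(sample_id, score, label)`.
#' @export
score_samples <- function(model, beta) {
  missing_p <- setdiff(model$features, rownames(beta))
  .stop_if(length(missing_p) > 0, "model probe(s) missing from beta: ",
           paste(utils::head(missing_p, 10), collapse = ", "))
  x <- t(beta[model$features, , drop = FALSE])
  score <- .model_scores(model, x)
  data.frame(sample_id = colnames(beta), score = as.numeric(score),
             label = ifelse(score > 0.5, "KdVS-like",
                            ifelse(score < 0.5, "control-like", "indeterminate")),
             stringsAsFactors = FALSE)
}

#' Save / load a classifier as JSON
#'
#' The serialized form carries the feature order, scaling constants, SVM
#' weights (or support vectors for the radial kernel), sigmoid calibration
#' coefficients and training metadata; reloading reproduces scores bitwise.
#'
#' @param model an `episig_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(m$sv)) m$sv <- as.matrix(m$sv)
  class(m) <- "episig_model"
  m
}

#' Cross-validated held-out scoring
#'
#' Stratified k-fold (or leave-one-out when `folds` is `NULL` or equals the
#' sample count): each sample is scored by a model never trained on it.
#'
#' @inheritParams train_classifier
#' @param folds number of folds; `NULL` for leave-one-out.
#' @return `data.frame(sample_id, label_true, score)` with attributes
#'   `sensitivity` and `specificity` at the 0.5 threshold.
#' @export
cross_validate <- function(beta, labels, signature_probes = rownames(beta),
                           params = list(kernel = "linear", cost = 1),
                           folds = NULL, seed = 1) {
  n <- ncol(beta)
  .stop_if(sum(labels == "case") < 2 || sum(labels == "control") < 2,
           "need >= 2 samples per class")
  if (is.null(folds)) folds <- n
  set.seed(seed)
  fold_id <- integer(n)
  for (cl in c("case", "control")) {  # stratified assignment
    ix <- which(labels == cl)
    .stop_if(folds < n && length(ix) < 2,
             "a class has a single member under stratified folds")
    fold_id[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  if (folds == n) fold_id <- seq_len(n)
  score <- numeric(n)
  for (f in unique(fold_id)) {
    test <- fold_id == f
    m <- suppressWarnings(train_classifier(
      beta[, !test, drop = FALSE], labels[!test], signature_probes,
      params, seed = seed + f))
    score[test] <- score_samples(m, beta[, test, drop = FALSE])$score
  }
  out <- data.frame(sample_id = colnames(beta), label_true = labels,
                    score = score, stringsAsFactors = FALSE)
  attr(out, "sensitivity") <- mean(score[labels == "case"] > 0.5)
  attr(out, "specificity") <- mean(score[labels == "control"] < 0.5)
  out
}

#' Score a panel of external cohorts
#'
#' Applies the model to each named cohort (e.g. other-syndrome specificity
#' panels) and reports per-cohort score summaries; no thresholding beyond
#' the 0.5 labeling rule.
#'
#' @param model an `episig_model`.
#' @param cohorts named list of beta matrices.
#' @return `data.frame(cohort, n, min, median, max)` with per-cohort score
#'   tables in attribute `"scores"`.
#' @export
specificity_panel <- function(model, cohorts) {
  if (length(cohorts) == 0)
    return(data.frame(cohort = character(0), n = integer(0), min = numeric(0),
                      median = numeric(0), max = numeric(0)))
  scores <- lapply(cohorts, function(b) score_samples(model, b))
  out <- data.frame(
    cohort = names(cohorts),
    n = vapply(scores, nrow, integer(1)),
    min = vapply(scores, function(s) min(s$score), numeric(1)),
    median = vapply(scores, function(s) stats::median(s$score), numeric(1)),
    max = vapply(scores, function(s) max(s$score), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "scores") <- scores
  out
}
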