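#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix with probes as rows and samples as
#' columns; every non-missing entry is a methylation fraction in \[0, 1\].
#' Missing entries (`NA`) are permitted before quality control and forbidden
#' after it.
#'
#' @param beta numeric matrix, probes x samples, with unique `rownames`
#'   (probe ids) and `colnames` (sample ids).
#' @param allow_missing logical; whether `NA` entries are acceptable.
#' @return `beta`, invisibly, if valid; otherwise an error naming the first
#'   offending probe/sample.
#' @export
validate_beta_matrix <- function(beta, allow_missing = TRUE) {
  .stop_if(!is.matrix(beta) || !is.numeric(beta), "beta must be a numeric matrix")
  .stop_if(is.null(rownames(beta)) || is.null(colnames(beta)),
           "beta must carry probe ids (rownames) and sample ids (colnames)")
  .stop_if(anyDuplicated(rownames(beta)) > 0, "duplicate probe ids in beta matrix")
  .stop_if(anyDuplicated(colnames(beta)) > 0, "duplicate sample ids in beta matrix")
  if (!allow_missing && anyNA(beta)) {
    bad <- which(is.na(beta), arr.ind = TRUE)[1, ]
    stop("missing beta value at probe ", rownames(beta)[bad[1]],
         ", sample ", colnames(beta)[bad[2]], call. = FALSE)
  }
  oob <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(oob) > 0) {
    stop("beta value out of [0,1] at probe ", rownames(beta)[oob[1, 1]],
         ", sample ", colnames(beta)[oob[1, 2]],
         " (value ", beta[oob[1, 1], oob[1, 2]], ")", call. = FALSE)
  }
  invisible(beta)
}

#' Read a beta-value matrix from delimited text
#'
#' Expects probes as rows: the first column holds probe ids, the header row
#' holds sample ids, and cells hold beta values or `NA`. Values outside
#' \[0, 1\] raise an error rather than being clamped.
#'
#' @param path file path.
#' @param dialect `"tab"` (default) or `"comma"`.
#' @return a validated numeric matrix (probes x samples).
#' @export
read_beta_matrix <- function(path, dialect = "tab") {
  df <- .read_table(path, dialect)
  .stop_if(ncol(df) < 2, "malformed beta matrix: need probe id column plus samples")
  ids <- as.character(df[[1]])
  .stop_if(anyDuplicated(ids) > 0, "duplicate probe ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_beta_matrix(m)
  m
}

#' Write a beta-value matrix as delimited text
#'
#' @inheritParams read_beta_matrix
#' @param beta validated beta matrix.
#' @return the path, invisibly.
#' @export
write_beta_matrix <- function(beta, path, dialect = "tab") {
  validate_beta_matrix(beta)
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_table(df, path, dialect, precise = TRUE)
}

#' Read a detection p-value matrix
#'
#' Same layout as [read_beta_matrix()]; values are per-probe, per-sample
#' detection p-values in \[0, 1\].
#'
#' @inheritParams read_beta_matrix
#' @return numeric matrix (probes x samples).
#' @export
read_detection_p <- function(path, dialect = "tab") {
  m <- read_beta_matrix(path, dialect)
  m
}

#' @rdname read_detection_p
#' @param detp detection p-value matrix.
#' @export
write_detection_p <- function(detp, path, dialect = "tab") {
  write_beta_matrix(detp, path, dialect)
}

# check that detp shares axes with its paired beta matrix
.check_paired_axes <- function(beta, detp) {
  .stop_if(!identical(rownames(beta), rownames(detp)) ||
             !identical(colnames(beta), colnames(detp)),
           "beta and detection-p matrices must share identical probe and sample axes")
  invisible(TRUE)
}
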