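.CHROMS <- c(paste0("chr", 1:22), "chrX", "chrY")
.ISLAND_RELATIONS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
.PROBE_CLASSES <- c("cg", "ch", "rs")

#' Read a probe annotation table
#'
#' BED-like delimited text with columns `probe_id`, `chromosome` (chr1..chr22,
#' chrX, chrY), `position` (1-based), `probe_class` (cg/ch/rs),
#' `island_relation` (Island, N_Shore, S_Shore, N_Shelf, S_Shelf, OpenSea),
#' `snp_maf` (minor-allele-frequency fraction, `NA` when no SNP overlaps),
#' and `cross_reactive` (TRUE/FALSE).
#'
#' @inheritParams read_sample_sheet
#' @return a validated `data.frame` keyed by `probe_id`.
#' @export
read_probe_annotation <- function(path, dialect = "tab") {
  df <- .read_table(path, dialect)
  needed <- c("probe_id", "chromosome", "position", "probe_class",
              "island_relation", "snp_maf", "cross_reactive")
  missing_cols <- setdiff(needed, names(df))
  .stop_if(length(missing_cols) > 0,
           "annotation missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, needed, drop = FALSE]
  df$probe_id <- as.character(df$probe_id)
  df$cross_reactive <- as.logical(df$cross_reactive)
  validate_probe_annotation(df)
  df
}

#' @rdname read_probe_annotation
#' @param ann annotation `data.frame`.
#' @export
write_probe_annotation <- function(ann, path, dialect = "tab") {
  validate_probe_annotation(ann)
  .write_table(ann, path, dialect)
}

#' @rdname read_probe_annotation
#' @export
validate_probe_annotation <- function(ann) {
  .stop_if(anyDuplicated(ann$probe_id) > 0, "duplicate probe_id in annotation")
  bad <- setdiff(unique(ann$chromosome), .CHROMS)
  .stop_if(length(bad) > 0, "unknown chromosome token(s): ", paste(bad, collapse = ", "))
  .stop_if(any(ann$position < 1), "annotation positions must be >= 1 (1-based)")
  bad <- setdiff(unique(ann$island_relation), .ISLAND_RELATIONS)
  .stop_if(length(bad) > 0, "unknown island_relation: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(ann$probe_class), .PROBE_CLASSES)
  .stop_if(length(bad) > 0, "unknown probe_class: ", paste(bad, collapse = ", "))
  .stop_if(any(!is.na(ann$snp_maf) & (ann$snp_maf < 0 | ann$snp_maf > 0.5)),
           "snp_maf must be in [0, 0.5] or NA")
  invisible(ann)
}

#' Read a gene annotation table
#'
#' BED-like delimited text with columns `gene`, `chromosome`, `start`, `end`
#' (1-based, inclusive).
#'
#' @inheritParams read_sample_sheet
#' @export
read_gene_annotation <- function(path, dialect = "tab") {
  df <- .read_table(path, dialect)
  needed <- c("gene", "chromosome", "start", "end")
  missing_cols <- setdiff(needed, names(df))
  .stop_if(length(missing_cols) > 0,
           "gene annotation missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, needed, drop = FALSE]
  .stop_if(anyDuplicated(df$gene) > 0, "duplicate gene symbol in annotation")
  .stop_if(any(df$start > df$end), "gene start must be <= end")
  df
}

#' @rdname read_gene_annotation
#' @param genes gene annotation `data.frame`.
#' @export
write_gene_annotation <- function(genes, path, dialect = "tab") {
  .write_table(genes, path, dialect)
}
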