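#' One-sided hypergeometric enrichment tail
#'
#' P(X >= k) for X ~ Hypergeometric(population N, K marked, n drawn),
#' evaluated in log space for numerical accuracy.
#'
#' @param k foreground hits, `K` marked in background, `n` foreground size,
#'   `N` background size.
#' @param K,n,N see above.
#' @return the upper-tail probability.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  .stop_if(k > n || K > N || n > N || k > K, "inconsistent urn counts")
  if (k <= 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' CpG island/shore enrichment of a signature
#'
#' Tests whether signature CpGs overlap CpG islands or shores (probes
#' annotated Island, N_Shore or S_Shore — i.e. within 2 kb of an island)
#' more often than background probes do, by a one-sided hypergeometric
#' test. Shelves and open sea are non-foreground. A two-sided variant
#' (doubled smaller tail, capped at 1) is available.
#'
#' @param signature a `signature` (or anything with `probe_id`).
#' @param ann probe annotation covering the background.
#' @param background character vector of background probe ids (e.g. all
#'   probes surviving QC); must contain the signature.
#' @param two_sided compute a two-sided p instead of the enrichment tail.
#' @return one-row `data.frame`: category, fg_hits, fg_size, bg_hits,
#'   bg_size, p, fraction_fg, fraction_bg.
#' @export
island_shore_enrichment <- function(signature, ann, background,
                                    two_sided = FALSE) {
  sig_ids <- signature$probe_id
  .stop_if(!all(sig_ids %in% background),
           "signature probes must be contained in the background")
  rel <- stats::setNames(ann$island_relation, ann$probe_id)
  .stop_if(anyNA(rel[background]), "background probe(s) missing from annotation")
  is_is <- rel %in% c("Island", "N_Shore", "S_Shore")
  names(is_is) <- ann$probe_id
  k <- sum(is_is[sig_ids]); n <- length(sig_ids)
  K <- sum(is_is[background]); N <- length(background)
  p <- hypergeom_tail(k, K, n, N)
  if (two_sided) {
    p_lo <- exp(stats::phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE))
    p <- min(1, 2 * min(p, p_lo))
  }
  data.frame(category = "island_or_shore", fg_hits = k, fg_size = n,
             bg_hits = K, bg_size = N, p = p,
             fraction_fg = k / n, fraction_bg = K / N,
             stringsAsFactors = FALSE)
}

#' Map signature CpGs to genes within a distance window
#'
#' A CpG maps to a gene when it lies on the same chromosome within the
#' closed interval \[start - window, end + window\] (1-based, inclusive;
#' strand-agnostic). One CpG may map to several genes. Default window is
#' 10 kb.
#'
#' @param signature a `signature` (or anything with `probe_id`).
#' @param ann probe annotation providing chromosome/position per probe.
#' @param genes gene annotation `data.frame(gene, chromosome, start, end)`.
#' @param window distance in bp (default 10000).
#' @return `data.frame(gene, n_cpg)` sorted by count descending; the full
#'   (probe_id, gene) pair table is in attribute `"pairs"`.
#' @export
map_genes <- function(signature, ann, genes, window = 10000) {
  a <- ann[match(signature$probe_id, ann$probe_id), ]
  .stop_if(anyNA(a$probe_id), "signature probe(s) missing from annotation")
  if (nrow(a) == 0 || nrow(genes) == 0) {
    out <- data.frame(gene = character(0), n_cpg = integer(0))
    attr(out, "pairs") <- data.frame(probe_id = character(0),
                                     gene = character(0))
    return(out)
  }
  cpg <- GenomicRanges::GRanges(a$chromosome,
                                IRanges::IRanges(a$position, a$position))
  gr <- GenomicRanges::GRanges(genes$chromosome,
                               IRanges::IRanges(pmax(1L, genes$start - window),
                                                genes$end + window))
  ov <- GenomicRanges::findOverlaps(cpg, gr)
  pairs <- data.frame(probe_id = a$probe_id[S4Vectors::queryHits(ov)],
                      gene = genes$gene[S4Vectors::subjectHits(ov)],
                      stringsAsFactors = FALSE)
  counts <- sort(table(pairs$gene), decreasing = TRUE)
  out <- data.frame(gene = names(counts), n_cpg = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "pairs") <- pairs
  out
}

#' Category enrichment over genes with reporting filters
#'
#' For each category (a named gene set), tests whether foreground genes hit
#' it more than expected under a one-sided hypergeometric draw from the
#' background gene universe. Categories with no background gene are not
#' tested; BH adjustment runs across the tested categories only. The
#' reporting filter (adjusted p < `alpha` and >= `min_hits` foreground gene
#' hits) is a pure post-process: set `report_all = TRUE` to see every
#' tested category with identical p-values.
#'
#' @param foreground,background character vectors of gene symbols
#'   (foreground must be a subset of background).
#' @param categories named list mapping category name to gene set.
#' @param alpha FDR threshold for reporting (default 0.05).
#' @param min_hits minimum foreground gene hits for reporting (default 3).
#' @param report_all return all tested categories, unfiltered.
#' @return `data.frame`: category, fg_hits, fg_size, bg_hits, bg_size, p,
#'   p_adj.
#' @export
category_enrichment <- function(foreground, background, categories,
                                alpha = 0.05, min_hits = 3,
                                report_all = FALSE) {
  .stop_if(length(background) == 0, "empty background gene universe")
  .stop_if(!all(foreground %in% background),
           "foreground genes must be contained in the background")
  foreground <- unique(foreground); background <- unique(background)
  rows <- lapply(names(categories), function(nm) {
    cat_bg <- intersect(categories[[nm]], background)
    if (length(cat_bg) == 0) return(NULL)
    k <- length(intersect(categories[[nm]], foreground))
    data.frame(category = nm, fg_hits = k, fg_size = length(foreground),
               bg_hits = length(cat_bg), bg_size = length(background),
               p = hypergeom_tail(k, length(cat_bg), length(foreground),
                                  length(background)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    return(data.frame(category = character(0), fg_hits = integer(0),
                      fg_size = integer(0), bg_hits = integer(0),
                      bg_size = integer(0), p = numeric(0), p_adj = numeric(0)))
  tab$p_adj <- adjust_bh(tab$p)
  if (!report_all)
    tab <- tab[tab$p_adj < alpha & tab$fg_hits >= min_hits, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Overlap between two tissue signatures
#'
#' @param sig_a,sig_b `signature` objects (need `probe_id`).
#' @param genes_a,genes_b character vectors of the genes underlying each
#'   signature (e.g. from [map_genes()]).
#' @return list with sorted `common_probes` and `common_genes`.
#' @export
cross_tissue_overlap <- function(sig_a, sig_b, genes_a = character(0),
                                 genes_b = character(0)) {
  list(common_probes = sort(intersect(sig_a$probe_id, sig_b$probe_id)),
       common_genes = sort(intersect(genes_a, genes_b)))
}

#' PCA of samples over a probe subset
#'
#' Centered (unscaled) principal-component analysis of samples using the
#' betas at the given probes; visualization plumbing for signature
#' clustering plots.
#'
#' @param beta beta matrix.
#' @param probes probe subset; defaults to all rows.
#' @return list with `coordinates` (samples x components) and
#'   `variance_fraction` (per component, non-increasing, summing to 1 when
#'   total variance is positive).
#' @export
pca_projection <- function(beta, probes = rownames(beta)) {
  missing_p <- setdiff(probes, rownames(beta))
  .stop_if(length(missing_p) > 0, "probe(s) missing from beta: ",
           paste(utils::head(missing_p, 5), collapse = ", "))
  .stop_if(ncol(beta) < 2, "need at least 2 samples")
  x <- t(beta[probes, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  vf <- if (total > 0) pc$sdev^2 / total else rep(0, length(pc$sdev))
  list(coordinates = pc$x, variance_fraction = vf)
}
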