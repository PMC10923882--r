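island_ann <- function(relations, ids = sprintf("cg%03d", seq_along(relations))) {
  data.frame(probe_id = ids, chromosome = "chr1",
             position = seq_along(ids) * 1000, probe_class = "cg",
             island_relation = relations, snp_maf = NA_real_,
             cross_reactive = FALSE, stringsAsFactors = FALSE)
}

test_that("hypergeometric tail matches closed form and full enumeration", {
  # 10 probes, 4 island/shore; drawing 3 that are all island/shore
  expect_equal(hypergeom_tail(3, 4, 3, 10), choose(4, 3) / choose(10, 3),
               tolerance = 1e-14)
  expect_equal(hypergeom_tail(0, 4, 3, 10), 1)
  set.seed(1)
  for (i in 1:40) {
    N <- sample(2:12, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_lt(abs(hypergeom_tail(k, K, n, N) - enumerate_hyper_tail(k, K, n, N)),
              1e-12)
  }
  expect_error(hypergeom_tail(5, 4, 3, 10), "inconsistent")
})

test_that("island/shore enrichment counts the foreground correctly", {
  ann <- island_ann(c("Island", "Island", "N_Shore", "S_Shore",
                      rep("OpenSea", 4), rep("N_Shelf", 2)))
  bg <- ann$probe_id
  sig <- data.frame(probe_id = ann$probe_id[c(1, 3, 4)])  # all island/shore
  rec <- island_shore_enrichment(sig, ann, bg)
  expect_equal(rec$fg_hits, 3)
  expect_equal(rec$bg_hits, 4)  # shelves and open sea are non-foreground
  expect_equal(rec$p, choose(4, 3) / choose(10, 3), tolerance = 1e-12)

  # foreground = background gives the certain event
  all_sig <- data.frame(probe_id = bg)
  expect_equal(island_shore_enrichment(all_sig, ann, bg)$p, 1)
  expect_error(island_shore_enrichment(
    data.frame(probe_id = "cg999"), ann, bg), "contained in the background")
})

test_that("gene mapping uses a closed 10 kb window and matches an all-pairs oracle", {
  genes <- data.frame(gene = c("A", "B"), chromosome = "chr1",
                      start = c(10000L, 100000L), end = c(20000L, 120000L))
  ann <- island_ann(rep("OpenSea", 3), ids = c("cg1", "cg2", "cg3"))
  ann$position <- c(5000L, 30000L, 29999L)  # cg2 exactly window bp from A's end
  sig <- data.frame(probe_id = c("cg1", "cg2", "cg3"))
  gm <- map_genes(sig, ann, genes, window = 10000)
  expect_equal(gm$gene, "A")
  expect_equal(gm$n_cpg, 3L)  # 5000 is 5 kb from start; 30000 exactly 10 kb from end

  # random fixture vs quadratic all-pairs oracle
  set.seed(2)
  ann_r <- island_ann(rep("OpenSea", 60))
  ann_r$chromosome <- sample(c("chr1", "chr2"), 60, TRUE)
  ann_r$position <- sample.int(2e5, 60)
  genes_r <- data.frame(gene = sprintf("G%02d", 1:25),
                        chromosome = sample(c("chr1", "chr2"), 25, TRUE),
                        start = sample.int(18e4, 25))
  genes_r$end <- genes_r$start + sample.int(3e4, 25)
  sig_r <- data.frame(probe_id = ann_r$probe_id)
  gm_r <- map_genes(sig_r, ann_r, genes_r, window = 10000)
  pairs <- attr(gm_r, "pairs")
  oracle <- 0
  for (i in seq_len(nrow(ann_r))) for (j in seq_len(nrow(genes_r))) {
    hit <- ann_r$chromosome[i] == genes_r$chromosome[j] &&
      ann_r$position[i] >= genes_r$start[j] - 10000 &&
      ann_r$position[i] <= genes_r$end[j] + 10000
    oracle <- oracle + hit
    expect_equal(any(pairs$probe_id == ann_r$probe_id[i] &
                       pairs$gene == genes_r$gene[j]), hit)
  }
  # count conservation: per-gene counts sum to the number of mapped pairs
  expect_equal(sum(gm_r$n_cpg), oracle)
  expect_false(is.unsorted(rev(gm_r$n_cpg)))
})

test_that("category enrichment applies the reporting filter as a pure post-process", {
  bg <- sprintf("G%02d", 1:40)
  fg <- bg[1:8]
  cats <- list(
    enriched_big = bg[1:10],        # 8 fg hits out of 10
    enriched_small = bg[c(1, 2)],   # 2 fg hits: excluded by min_hits
    flat = bg,                      # equals background: p = 1
    absent = c("X1", "X2"))         # no background gene: not tested
  full <- category_enrichment(fg, bg, cats, report_all = TRUE)
  expect_equal(nrow(full), 3)  # 'absent' untested
  expect_equal(full$p[full$category == "flat"], 1)
  filt <- category_enrichment(fg, bg, cats, alpha = 0.05, min_hits = 3)
  expect_equal(filt$category, "enriched_big")
  # the filter never changes p-values
  expect_equal(filt$p, full$p[full$category == "enriched_big"])
  expect_equal(filt$p_adj, full$p_adj[full$category == "enriched_big"])

  # the well-powered but low-hit category stays excluded even when significant
  cats2 <- list(tiny = bg[1:2])
  full2 <- category_enrichment(fg, bg, cats2, report_all = TRUE)
  expect_lt(full2$p_adj, 0.05)
  expect_equal(nrow(category_enrichment(fg, bg, cats2)), 0)

  # p-values agree with the enumeration oracle on a 5-category fixture
  set.seed(3)
  bg_s <- sprintf("H%02d", 1:11)
  fg_s <- sample(bg_s, 5)
  cats_s <- lapply(1:5, function(i) sample(bg_s, sample(2:8, 1)))
  names(cats_s) <- paste0("c", 1:5)
  got <- category_enrichment(fg_s, bg_s, cats_s, report_all = TRUE)
  for (i in 1:5) {
    k <- length(intersect(cats_s[[i]], fg_s))
    expect_lt(abs(got$p[got$category == paste0("c", i)] -
                    enumerate_hyper_tail(k, length(cats_s[[i]]), 5, 11)), 1e-12)
  }
  expect_error(category_enrichment(fg, character(0), cats), "empty background")
})

test_that("cross-tissue overlap returns sorted intersections", {
  sa <- data.frame(probe_id = c("cg3", "cg1", "cg2"))
  sb <- data.frame(probe_id = c("cg9", "cg2"))
  ov <- cross_tissue_overlap(sa, sb, c("APC2", "ORMDL3", "REEP3", "WT1"),
                             c("REEP3", "APC2", "SHANK2", "ORMDL3"))
  expect_equal(ov$common_probes, "cg2")
  expect_equal(ov$common_genes, c("APC2", "ORMDL3", "REEP3"))
  none <- cross_tissue_overlap(data.frame(probe_id = "a"),
                               data.frame(probe_id = "b"))
  expect_length(none$common_probes, 0)
  expect_length(none$common_genes, 0)
  full <- cross_tissue_overlap(sa, sa, c("X"), c("X"))
  expect_equal(full$common_probes, sort(sa$probe_id))
})

test_that("PCA projection handles degenerate and rank-1 structure", {
  b <- matrix(0.4, 20, 2, dimnames = list(sprintf("cg%03d", 1:20), c("a", "b")))
  pc <- pca_projection(b)
  expect_true(all(pc$variance_fraction == 0))

  # rank-1: sample loadings along a single direction
  set.seed(4)
  u <- runif(30); v <- c(0, 0.2, 0.4, 0.6)
  r1 <- outer(u, v)
  dimnames(r1) <- list(sprintf("cg%03d", 1:30), paste0("s", 1:4))
  pc1 <- pca_projection(r1)
  expect_equal(pc1$variance_fraction[1], 1, tolerance = 1e-12)

  rnd <- random_beta(50, 6, seed = 5)
  pcr <- pca_projection(rnd)
  expect_lte(sum(pcr$variance_fraction), 1 + 1e-12)
  expect_false(is.unsorted(rev(pcr$variance_fraction)))
  expect_error(pca_projection(rnd[, 1, drop = FALSE]), "at least 2 samples")
})
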