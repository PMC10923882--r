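# Fixture builders and independent oracles shared across test files.

# The eight discovery-cohort subjects (id, sex, age) used for the cohort
# worked example.
discovery_sheet <- function() {
  data.frame(
    sample_id = paste0("EX", 1:8),
    group = "case",
    age = c(8, 3, 11, 15.5, 5, 10, 4.5, 10),
    sex = c("M", "M", "M", "F", "F", "F", "M", "F"),
    tissue = "blood",
    cohort = "discovery",
    stringsAsFactors = FALSE)
}

write_sheet_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_beta <- function(n_probes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

# Independent oracle: upper hypergeometric tail by full enumeration of all
# n-subsets of a population of size N with K marked elements.
enumerate_hyper_tail <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  marked <- seq_len(K)  # wlog the first K elements are marked
  hits <- apply(subsets, 2, function(s) sum(s %in% marked))
  mean(hits >= k)
}

# Independent oracle: Benjamini-Hochberg step-up by explicit sort and
# cumulative minimum from the largest rank.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- (n / seq_len(n)) * p[o]
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Independent oracle: greedy sex/age matching re-simulated directly on the
# data frames, selecting one pool row at a time.
greedy_match_oracle <- function(cases, pool, ratio) {
  avail <- rep(TRUE, nrow(pool))
  sel <- integer(0)
  for (i in seq_len(nrow(cases))) {
    for (r in seq_len(ratio)) {
      idx <- which(avail & pool$sex == cases$sex[i])
      if (length(idx) == 0) break
      best <- idx[order(abs(pool$age[idx] - cases$age[i]), idx)[1]]
      avail[best] <- FALSE
      sel <- c(sel, best)
    }
  }
  pool[sel, , drop = FALSE]
}

# Random simplex rows (independent of the package's Dirichlet sampler).
random_simplex <- function(n, k = 6, seed = 103) {
  set.seed(seed)
  w <- matrix(rexp(n * k), n, k)
  w / rowSums(w)
}

# Separable two-class fixture for classifier tests: strong planted effect,
# low noise.
separable_fixture <- function(seed = 11, n_cases = 10, n_controls = 20) {
  cfg <- simulation_config(n_probes = 2000, n_cases = n_cases,
                           n_controls = n_controls,
                           n_signature_probes = 60,
                           effect_size_range = c(0.2, 0.2),
                           noise_sd = 0.1, seed = seed)
  simulate_cohort(cfg)
}
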