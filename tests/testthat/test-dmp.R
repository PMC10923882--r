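make_design_sheet <- function(n_cases = 8, n_controls = 21, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%03d", seq_len(n_cases + n_controls)),
             group = rep(c("case", "control"), c(n_cases, n_controls)),
             age = round(runif(n_cases + n_controls, 3, 15), 1),
             sex = sample(c("M", "F"), n_cases + n_controls, TRUE),
             tissue = "blood", cohort = "discovery",
             stringsAsFactors = FALSE)
}

test_that("design matrix has the fixed column order and drops constants with a warning", {
  sheet <- make_design_sheet()
  props <- matrix(rgamma(29 * 6, 2), 29, 6,
                  dimnames = list(sheet$sample_id,
                                  c("Neu", "CD4T", "CD8T", "Bcell", "NK", "Mono")))
  props <- props / rowSums(props)
  X <- build_design(sheet, props)
  expect_equal(colnames(X),
               c("intercept", "group", "age", "sexM",
                 "CD4T", "CD8T", "Bcell", "NK", "Mono"))
  expect_equal(ncol(X), 9)
  expect_equal(unname(X[, "group"]), as.numeric(sheet$group == "case"))

  flat <- sheet
  flat$age <- 7
  expect_warning(X2 <- build_design(flat), "constant design column")
  expect_false("age" %in% colnames(X2))

  bad <- sheet
  bad$group[1] <- "unknown"
  expect_error(build_design(bad), "unknown group")
})

test_that("OLS fits match a per-probe normal-equations oracle to 1e-10", {
  sheet <- make_design_sheet(seed = 2)
  X <- build_design(sheet)
  set.seed(3)
  beta <- matrix(runif(200 * 29, 0.05, 0.95), 200, 29,
                 dimnames = list(sprintf("cg%04d", 1:200), sheet$sample_id))
  fits <- fit_linear_models(beta, X)
  xtx_inv <- solve(t(X) %*% X)
  for (i in seq(1, 200, by = 7)) {
    b_hat <- xtx_inv %*% t(X) %*% beta[i, ]
    res <- beta[i, ] - X %*% b_hat
    s2 <- sum(res^2) / (29 - ncol(X))
    expect_lt(abs(fits$coef[i] - b_hat["group", 1]), 1e-10)
    expect_lt(abs(fits$s2[i] - s2), 1e-10)
    expect_lt(abs(fits$se[i] - sqrt(s2 * xtx_inv["group", "group"])), 1e-10)
  }
  expect_true(all(fits$df == 29 - ncol(X)))
})

test_that("exact linear responses give zero residual variance and closed-form coefficients", {
  sheet <- make_design_sheet(seed = 4)
  X <- build_design(sheet)
  y <- as.numeric(0.3 + 0.1 * X[, "group"] + 0.01 * X[, "age"])
  beta <- rbind(lin = y, rand = runif(29, 0.2, 0.8))
  colnames(beta) <- sheet$sample_id
  fits <- fit_linear_models(beta, X)
  expect_equal(fits$s2[1], 0, tolerance = 1e-20)
  expect_equal(fits$coef[1], 0.1, tolerance = 1e-12)

  # two-group design without covariates: coefficient = difference of means
  X0 <- cbind(intercept = 1, group = as.numeric(sheet$group == "case"))
  rownames(X0) <- sheet$sample_id
  f0 <- fit_linear_models(beta, X0)
  md <- mean(beta["rand", sheet$group == "case"]) -
    mean(beta["rand", sheet$group == "control"])
  expect_equal(f0$coef[2], md, tolerance = 1e-12)
})

test_that("moderation limits: identical variances and fixed prior df", {
  sheet <- make_design_sheet(seed = 5)
  X <- build_design(sheet)
  set.seed(6)
  beta <- matrix(runif(50 * 29, 0.1, 0.9), 50, 29,
                 dimnames = list(sprintf("cg%04d", 1:50), sheet$sample_id))
  fits <- fit_linear_models(beta, X)

  # d0 = 0: moderated t collapses to the ordinary t for every probe
  m0 <- moderate(fits, prior_df = 0)
  expect_equal(m0$t, fits$coef / fits$se, tolerance = 1e-12)

  # d0 = Inf: every probe is fully pooled to the mean variance
  mi <- moderate(fits, prior_df = Inf)
  expect_equal(attr(mi, "s0_2"), mean(fits$s2), tolerance = 1e-12)
  expect_equal(mi$t, fits$coef / (fits$stdev_unscaled * sqrt(mean(fits$s2))),
               tolerance = 1e-12)

  # probes sharing one variance: the empirical prior is that variance and
  # moderated t equals ordinary t
  dup <- beta[rep(1, 10), ]
  rownames(dup) <- sprintf("cg%04d", 1:10)
  fd <- fit_linear_models(dup, X)
  md <- moderate(fd)
  expect_equal(attr(md, "s0_2"), fd$s2[1], tolerance = 1e-12)
  expect_equal(md$t, fd$coef / fd$se, tolerance = 1e-12)
})

test_that("moderation matches the reference empirical-Bayes implementation", {
  sheet <- make_design_sheet(seed = 7)
  X <- build_design(sheet)
  set.seed(8)
  # heterogeneous true variances so the prior df is finite
  sds <- runif(300, 0.02, 0.2)
  beta <- 0.5 + matrix(rnorm(300 * 29), 300, 29) * sds
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(sprintf("cg%04d", 1:300), sheet$sample_id)
  fits <- fit_linear_models(beta, X)
  mod <- moderate(fits)
  lf <- limma::eBayes(limma::lmFit(beta, X))
  expect_equal(attr(mod, "d0"), lf$df.prior, tolerance = 1e-9)
  expect_equal(attr(mod, "s0_2"), lf$s2.prior, tolerance = 1e-9)
  expect_equal(mod$t, unname(lf$t[, "group"]), tolerance = 1e-9)
  expect_equal(mod$p, unname(lf$p.value[, "group"]), tolerance = 1e-9)
})

test_that("BH adjustment matches hand computation and a sort-based oracle exactly", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  set.seed(9)
  for (n in c(1, 2, 10, 101)) {
    p <- runif(n)
    expect_identical(adjust_bh(p), bh_oracle(p))
    # permutation invariance (up to the same permutation)
    perm <- sample(n)
    expect_identical(adjust_bh(p[perm]), adjust_bh(p)[perm])
    expect_true(all(adjust_bh(p) >= p))
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("delta beta is the raw difference of group means", {
  beta <- matrix(c(0.6, 0.6, 0.45, 0.45,
                   0.2, 0.2, 0.2, 0.2), 2, 4, byrow = TRUE,
                 dimnames = list(c("cg1", "cg2"), paste0("s", 1:4)))
  groups <- c("case", "case", "control", "control")
  d <- delta_beta(beta, groups)
  expect_equal(unname(d), c(0.15, 0))
  expect_error(delta_beta(beta, rep("case", 4)), "non-empty")
})

test_that("signature selection applies strict dual thresholds and deterministic ordering", {
  res <- data.frame(probe_id = c("cg1", "cg2", "cg3", "cg4", "cg5"),
                    p_adj = c(0.04, 0.04, 0.06, 0.01, 0.01),
                    delta_beta = c(0.12, 0.08, 0.5, -0.2, 0.2))
  sig <- select_signature(res, alpha = 0.05, delta = 0.10)
  # cg2 excluded (|delta| <= 0.10), cg3 excluded (p_adj >= 0.05)
  expect_equal(sig$probe_id, c("cg4", "cg5", "cg1"))
  expect_equal(sig$direction, c("hypo", "hyper", "hyper"))
  expect_true(all(sig$p_adj < 0.05 & abs(sig$delta_beta) > 0.10))

  none <- select_signature(res, alpha = 1e-6, delta = 0.9)
  expect_equal(nrow(none), 0)
  path <- tempfile(fileext = ".tsv")
  write_signature(none, path)  # empty signature is serializable
  expect_equal(nrow(read_signature(path)), 0)
})

test_that("the variance filter keeps probes by strict range threshold", {
  beta <- rbind(narrow = seq(0.40, 0.46, length.out = 6),
                wide = seq(0.30, 0.55, length.out = 6))
  colnames(beta) <- paste0("s", 1:6)
  out <- variance_filter(beta, min_range = 0.10)
  expect_equal(rownames(out$beta), "wide")
  expect_equal(out$removed, 1)

  set.seed(10)
  rand <- matrix(runif(50 * 8), 50, 8,
                 dimnames = list(sprintf("cg%03d", 1:50), paste0("s", 1:8)))
  all_kept <- variance_filter(rand, min_range = 0)
  expect_identical(all_kept$beta, rand)

  # planted high-variance probes recovered exactly
  low <- matrix(0.5 + runif(300 * 10, 0, 0.04), 300, 10)
  high <- matrix(runif(40 * 10, 0.1, 0.9), 40, 10)
  high[, 1] <- 0.05; high[, 2] <- 0.95  # guarantee range > 0.10
  m <- rbind(low, high)
  dimnames(m) <- list(sprintf("cg%04d", 1:340), paste0("s", 1:10))
  out2 <- variance_filter(m, min_range = 0.10)
  expect_setequal(rownames(out2$beta), sprintf("cg%04d", 301:340))
})

test_that("power at the dual thresholds increases with planted effect size", {
  sens <- sapply(c(0.10, 0.15), function(d) {
    cfg <- simulation_config(n_probes = 3000, n_signature_probes = 60,
                             effect_size_range = c(d, d), seed = 77)
    sim <- simulate_cohort(cfg)
    res <- dm_analysis(sim$beta, sim$sheet)
    sig <- select_signature(res)
    mean(sim$truth$signature$probe_id %in% sig$probe_id)
  })
  expect_gt(sens[2], sens[1])
})
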