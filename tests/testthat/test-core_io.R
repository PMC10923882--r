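test_that("beta matrix round-trips bitwise and rejects out-of-range values", {
  b <- random_beta(50, 10, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_beta_matrix(b, path)
  b2 <- read_beta_matrix(path)
  expect_identical(dimnames(b2), dimnames(b))
  expect_true(all(b2 == b))  # write.table prints full precision

  bad <- b
  bad[2, 4] <- 1.2
  path2 <- tempfile(fileext = ".tsv")
  df <- data.frame(probe_id = rownames(bad), bad, check.names = FALSE)
  utils::write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  err <- expect_error(read_beta_matrix(path2), "out of \\[0,1\\]")
  expect_match(conditionMessage(err), rownames(b)[2])
  expect_match(conditionMessage(err), colnames(b)[4])

  dup <- rbind(b, b[1, , drop = FALSE])
  expect_error(validate_beta_matrix(dup), "duplicate probe ids")
})

test_that("sample sheet reader validates vocabularies and parses the discovery cohort", {
  sheet <- discovery_sheet()
  got <- read_sample_sheet(write_sheet_fixture(sheet))
  expect_equal(nrow(got), 8)
  expect_equal(sum(got$sex == "F"), 4)
  expect_equal(sum(got$sex == "M"), 4)
  expect_equal(got$age, sheet$age)

  # case-insensitive headers
  up <- sheet
  names(up) <- toupper(names(up))
  expect_equal(read_sample_sheet(write_sheet_fixture(up))$sample_id,
               sheet$sample_id)

  # empty data section is fine
  empty <- sheet[0, ]
  expect_equal(nrow(read_sample_sheet(write_sheet_fixture(empty))), 0)

  bad_sex <- sheet; bad_sex$sex[1] <- "X"
  expect_error(read_sample_sheet(write_sheet_fixture(bad_sex)), "invalid sex")
  expect_error(read_sample_sheet(write_sheet_fixture(sheet[, -3])),
               "missing column")
  dup <- rbind(sheet, sheet[1, ])
  expect_error(read_sample_sheet(write_sheet_fixture(dup)), "duplicate sample_id")
})

test_that("cohort summary reproduces the discovery demographics and a closed form", {
  s <- cohort_summary(discovery_sheet())
  expect_equal(round(s$age_mean, 1), 8.4)
  expect_equal(round(s$age_sd, 1), 4.1)
  expect_equal(s$n, 8)
  expect_equal(s$n_female, 4)

  tri <- data.frame(sample_id = letters[1:3], sex = "F", age = c(2, 4, 6))
  s3 <- cohort_summary(tri)
  expect_equal(s3$age_mean, 4)
  expect_equal(s3$age_sd, 2)

  # independent two-pass mean/SD oracle on random ages
  set.seed(5)
  ages <- runif(30, 0, 60)
  df <- data.frame(sample_id = paste0("s", 1:30),
                   sex = sample(c("M", "F"), 30, TRUE), age = ages)
  s30 <- cohort_summary(df)
  mu <- sum(ages) / 30
  sd2 <- sqrt(sum((ages - mu)^2) / 29)
  expect_lt(abs(s30$age_mean - mu), 1e-12)
  expect_lt(abs(s30$age_sd - sd2), 1e-12)

  expect_error(cohort_summary(df[0, ]), "at least one record")
  expect_true(is.na(cohort_summary(df[1, ])$age_sd))
})

test_that("greedy control matching picks nearest same-sex pool members", {
  case <- data.frame(sample_id = "c1", sex = "F", age = 10)
  pool <- data.frame(sample_id = paste0("p", 1:3), sex = c("F", "F", "M"),
                     age = c(9, 20, 10))
  got <- match_controls(case, pool, ratio = 1)
  expect_equal(got$sample_id, "p1")

  # no same-sex member: zero matches, warning
  pool_m <- data.frame(sample_id = "p1", sex = "M", age = 10)
  expect_warning(got0 <- match_controls(case, pool_m, ratio = 1),
                 "no available same-sex match")
  expect_equal(nrow(got0), 0)
})

test_that("matching equals an independent greedy re-simulation and never reuses members", {
  set.seed(17)
  for (rep in 1:5) {
    cases <- data.frame(sample_id = paste0("c", 1:8),
                        sex = sample(c("M", "F"), 8, TRUE),
                        age = round(runif(8, 1, 20), 1))
    pool <- data.frame(sample_id = paste0("p", 1:50),
                       sex = sample(c("M", "F"), 50, TRUE),
                       age = round(runif(50, 1, 20), 1))
    got <- suppressWarnings(match_controls(cases, pool, ratio = 2))
    want <- suppressWarnings(greedy_match_oracle(cases, pool, ratio = 2))
    expect_equal(got$sample_id, want$sample_id)
    expect_equal(anyDuplicated(got$sample_id), 0)
    expect_length(intersect(got$sample_id, cases$sample_id), 0)
    expect_lte(nrow(got), 2 * nrow(cases))
  }
})

test_that("probe annotation round-trips simulator truth and rejects bad vocabularies", {
  sim <- simulate_cohort(simulation_config(n_probes = 300, seed = 2,
                                           n_signature_probes = 10,
                                           qc_fail = c(detection = 3, snp = 5,
                                                       cross_reactive = 2,
                                                       extreme_beta = 2,
                                                       non_cpg = 2,
                                                       sex_chromosome = 6)))
  path <- tempfile(fileext = ".tsv")
  write_probe_annotation(sim$annotation, path)
  got <- read_probe_annotation(path)
  ann <- sim$annotation
  attributes(ann)[c("qc_sets", "clean_pool")] <- NULL
  expect_equal(got, ann, ignore_attr = TRUE)

  bad <- ann
  bad$island_relation[1] <- "Sea"
  expect_error(validate_probe_annotation(bad), "unknown island_relation")
  bad2 <- ann
  bad2$chromosome[1] <- "chr23"
  expect_error(validate_probe_annotation(bad2), "unknown chromosome")
})
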