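test_that("identical config and seed reproduce the table byte-for-byte", {
  cfg <- paper_like_scenario(seed = 33L)
  t1 <- generate_samples(cfg)$table
  t2 <- generate_samples(cfg)$table
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_sample_table(t1, p1); write_sample_table(t2, p2)
  expect_identical(readLines(p1), readLines(p2))
  t3 <- generate_samples(paper_like_scenario(seed = 34L))$table
  expect_false(identical(t3$d15N, t1$d15N))
})

test_that("clean groups conserve counts through QC", {
  gen <- generate_samples(scenario_config(
    groups = list(group_spec("wildcat", "Hainich", 2, 38,
                             mu = c(-20.5, 3.6, 4.4),
                             sigma = c(1.4, 1.7, 1.1), qc_fail_rate = 0)),
    seed = 3L))
  expect_equal(nrow(gen$table), 38)
  res <- apply_qc(gen$table)
  expect_equal(res$report$totals$n_retained, 38)
})

test_that("the paper-like scenario reproduces the study's QC structure", {
  gen <- generate_samples(paper_like_scenario(seed = 8L))
  expect_equal(nrow(gen$table), 78)
  expect_s3_class(gen$table, "sample_table")   # passes schema validation
  res <- apply_qc(gen$table)
  expect_equal(res$report$totals$n_input, 72 + 6)
  expect_equal(res$report$totals$n_retained, 72)
  reasons <- res$report$per_sample$reasons[!res$report$per_sample$retained]
  expect_equal(sum(grepl("cn_out_of_range", reasons)), 5)
  expect_equal(sum(grepl("pctC_high", reasons)), 1)
  tab <- res$table
  expect_equal(sum(tab$taxon == "wildcat"), 38)
  expect_equal(sum(tab$taxon == "domestic_cat"), 23)
  expect_equal(sum(tab$taxon == "hybrid"), 11)
})

test_that("group means match the configured truth at large n", {
  gen <- generate_samples(paper_like_scenario(seed = 12L, n_scale = 263))
  tab <- correct_d13c(apply_qc(gen$table)$table)
  wc <- tab[tab$taxon == "wildcat", ]
  expect_gt(nrow(wc), 9900)
  # pooled wildcat means implied by the group table
  expect_equal(mean(wc$d15N), 3.58, tolerance = 0.05 / 3.58)
  expect_equal(mean(wc$d13C_cor), -20.49, tolerance = 0.05 / 20.49)
})

test_that("SEAc of a generated group recovers the configured covariance", {
  gen <- generate_samples(scenario_config(
    groups = list(group_spec("wildcat", "Hainich", 2, 1000,
                             mu = c(-20.5, 3.6, 4.4),
                             sigma = c(1.4, 1.7, 1.1))),
    seed = 14L))
  tab <- correct_d13c(apply_qc(gen$table)$table)
  fit <- fit_standard_ellipse(tab$d13C_cor, tab$d15N)
  truth <- pi * 1.4 * 1.7
  expect_lt(abs(fit$SEAc - truth) / truth, 0.10)
})

test_that("a configured year trend is recovered by the trend fitter", {
  cfg <- scenario_config(
    groups = list(group_spec("wildcat", "Hainich", 2, 200,
                             mu = c(-20.5, 3.6, 4.4),
                             sigma = c(1.2, 1.7, 1.1))),
    covariates = covariate_spec(year_effect = c(d13C_cor = 0.10)),
    seed = 15L)
  tab <- correct_d13c(apply_qc(generate_samples(cfg)$table)$table)
  fit <- fit_trend(tab$year, tab$d13C_cor, "ols")
  expect_lt(abs(fit$slope - 0.10), 0.04)
})

test_that("the sex contrast is recovered with the configured sign and size", {
  cfg <- scenario_config(
    groups = list(group_spec("wildcat", "Hainich", 2, 2000,
                             mu = c(-20.5, 3.6, 4.4),
                             sigma = c(1.2, 1.7, 1.1))),
    covariates = covariate_spec(sex_effect = c(d13C_cor = -1.0, d15N = 0.8)),
    seed = 16L)
  tab <- correct_d13c(apply_qc(generate_samples(cfg)$table)$table)
  d13_gap <- mean(tab$d13C_cor[tab$sex == "male"]) -
    mean(tab$d13C_cor[tab$sex == "female"])
  d15_gap <- mean(tab$d15N[tab$sex == "male"]) -
    mean(tab$d15N[tab$sex == "female"])
  expect_equal(d13_gap, -1.0, tolerance = 0.15)
  expect_equal(d15_gap, 0.8, tolerance = 0.2)
})

test_that("the truth record round-trips through JSON", {
  gen <- generate_samples(paper_like_scenario(seed = 20L))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(gen$truth, path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path)
  expect_equal(back$seed, 20L)
  expect_equal(length(back$groups), length(gen$truth$groups))
  expect_equal(unlist(back$groups[[1]]$mu), gen$truth$groups[[1]]$mu)
  expect_equal(back$covariates$year_effect$d13C_cor,
               gen$truth$covariates$year_effect$d13C_cor)
})

test_that("invalid group specs are rejected at configuration time", {
  bad_sigma <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)  # not PSD
  expect_error(group_spec("wildcat", "Hainich", 2, 5,
                          mu = c(-20, 3, 4), sigma = bad_sigma),
               "positive definite")
  expect_error(scenario_config(list(), seed = 1), "groups")
})
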