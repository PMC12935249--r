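test_that("atomic ratios follow the mass-to-atom conversion", {
  expect_equal(atomic_ratios(45, 15)$c_n, 3.5007, tolerance = 1e-4)
  expect_equal(atomic_ratios(40, 20)$c_n, 2.3338, tolerance = 1e-4)
  # hand evaluation: (45*32.060)/(0.20*12.007), (15*32.060)/(0.20*14.011)
  r <- atomic_ratios(45, 15, 0.20)
  expect_equal(r$c_s, 600.7745, tolerance = 1e-3)
  expect_equal(r$n_s, 171.6152, tolerance = 1e-3)
  expect_true(is.na(atomic_ratios(45, 15)$c_s))
  expect_error(atomic_ratios(0, 15), "positive")
  expect_error(atomic_ratios(45, -1), "positive")
  expect_error(atomic_ratios(45, 15, 0), "pctS")
})

test_that("QC retention rule honours every boundary exactly", {
  df <- make_raw_df(6)
  # row 1: clean. row 2: C/N too high (depress pctN). row 3: pctC exactly 50
  # (retained: rule is strictly greater). row 4: pctC just above 50.
  # row 5: pctN above 20. row 6: region missing.
  df$pctN[2] <- df$pctC[2] * 14.011 / (12.007 * 4.5)   # c_n = 4.5
  df$pctC[3] <- 50.0
  df$pctN[3] <- 50.0 * 14.011 / (12.007 * 3.5)         # keep c_n in window
  df$pctC[4] <- 50.0001
  df$pctN[4] <- df$pctC[4] * 14.011 / (12.007 * 3.5)
  df$pctN[5] <- 21
  df$pctC[5] <- 21 * 12.007 * 3.5 / 14.011             # c_n back in window
  df$region[6] <- NA
  tab <- as_sample_table(df)

  res <- apply_qc(tab)
  ps <- res$report$per_sample
  expect_identical(ps$retained, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_match(ps$reasons[2], "cn_out_of_range")
  expect_match(ps$reasons[4], "pctC_high")
  expect_match(ps$reasons[5], "pctN_high")
  expect_match(ps$reasons[6], "missing_region")
  expect_identical(res$table$sample_id, df$sample_id[c(1, 3)])

  # C/N window edges are inclusive
  df2 <- make_raw_df(2)
  df2$pctN[1] <- df2$pctC[1] * 14.011 / (12.007 * 3.0)
  df2$pctN[2] <- df2$pctC[2] * 14.011 / (12.007 * 4.05)
  expect_true(all(apply_qc(as_sample_table(df2))$report$per_sample$retained))

  t <- res$report$totals
  expect_equal(t$n_input, t$n_retained + sum(!ps$retained))
  expect_true(all(nchar(ps$reasons[!ps$retained]) > 0))

  # missing region is tolerated when not required
  res2 <- apply_qc(tab, qc_config(require_region = FALSE))
  expect_true(res2$report$per_sample$retained[6])
})

test_that("QC is idempotent", {
  gen <- generate_samples(scenario_config(
    groups = list(group_spec("wildcat", "Hainich", 2, 60,
                             mu = c(-20.5, 3.6, 4.4), sigma = c(1.4, 1.7, 1.1),
                             qc_fail_rate = 0.3)),
    seed = 11L))
  first <- apply_qc(gen$table)
  second <- apply_qc(first$table)
  expect_equal(second$report$totals$n_excluded, 0)
  expect_identical(as.data.frame(second$table), as.data.frame(first$table))
})

test_that("keratin-like synthetic samples are retained at >= 99% without contamination", {
  gen <- generate_samples(scenario_config(
    groups = list(group_spec("wildcat", "Hainich", 2, 2000,
                             mu = c(-20.5, 3.6, 4.4),
                             sigma = c(1.4, 1.7, 1.1))),
    seed = 5L))
  res <- apply_qc(gen$table)
  expect_gte(res$report$totals$n_retained / res$report$totals$n_input, 0.99)
})

test_that("contamination injection matches the configured rate within binomial error", {
  rate <- 0.2
  gen <- generate_samples(scenario_config(
    groups = list(group_spec("wildcat", "Hainich", 2, 1000,
                             mu = c(-20.5, 3.6, 4.4),
                             sigma = c(1.4, 1.7, 1.1),
                             qc_fail_rate = rate)),
    seed = 21L))
  res <- apply_qc(gen$table)
  frac <- res$report$totals$n_excluded / res$report$totals$n_input
  expect_lt(abs(frac - rate), 4 * sqrt(rate * (1 - rate) / 1000) + 0.01)
})

test_that("advisory sulfur windows flag but never exclude", {
  df <- make_raw_df(2)
  df$pctS <- c(0.2, 5)   # second: C/S far below 300
  res <- apply_qc(as_sample_table(df))
  expect_true(all(res$report$per_sample$retained))
  expect_match(res$report$per_sample$advisory_flags[2], "cs_out_of_range")
})
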