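test_that("collection months partition into growth seasons", {
  expect_identical(assign_season(12), "summer_grown")
  expect_identical(assign_season(7), "winter_grown")
  expect_identical(assign_season(NA), "unclassified")
  labels <- assign_season(1:12)
  expect_identical(sort(unique(labels)), c("summer_grown", "winter_grown"))
  expect_identical(which(labels == "summer_grown"), c(1:4, 12L))
  expect_error(assign_season(13), "1..12")
  expect_error(assign_season(0), "1..12")
})

test_that("OLS trend fit recovers exact and constant lines", {
  yrs <- 2000:2009
  f <- fit_trend(yrs, 2 * yrs, "ols")
  expect_equal(f$slope, 2.0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1.0, tolerance = 1e-12)
  f0 <- fit_trend(yrs, rep(5, 10), "ols")
  expect_equal(f0$slope, 0.0, tolerance = 1e-12)
  expect_error(fit_trend(rep(2000, 5), stats::rnorm(5)), "identical")
  expect_error(fit_trend(2000:2001, c(1, 2)), "n >= 3")
})

test_that("the Huber fit resists a gross outlier and matches hand-rolled IRLS", {
  x <- 1:10
  y <- as.numeric(x)   # nine points on y = x ...
  y[10] <- 30          # ... plus one gross outlier
  ols <- fit_trend(x, y, "ols")
  hub <- fit_trend(x, y, "huber")
  expect_lt(abs(hub$slope - 1.0), abs(ols$slope - 1.0))
  oracle <- hand_huber(x, y)
  expect_equal(hub$intercept, oracle[1], tolerance = 0.02)
  expect_equal(hub$slope, oracle[2], tolerance = 0.02)
  # r_squared column always carries the OLS value
  expect_equal(hub$r_squared, ols$r_squared)
})

test_that("Huber equals OLS when no residual is down-weighted", {
  x <- 1:12
  y <- 0.5 * x + c(-1, 1)[1 + x %% 2] * 1e-3  # tiny symmetric residuals
  ols <- fit_trend(x, y, "ols")
  hub <- fit_trend(x, y, "huber")
  expect_equal(hub$slope, ols$slope, tolerance = 1e-6)
  expect_equal(hub$intercept, ols$intercept, tolerance = 1e-6)
})

test_that("rank-sum tests match exact enumeration and the BH hand oracle", {
  res <- pairwise_wilcoxon(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$p_raw, 0.1, tolerance = 1e-12)
  expect_equal(res$statistic, 6)  # rank-sum of the first group
  expect_true(res$exact)

  same <- pairwise_wilcoxon(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$p_raw, 1.0)

  # three groups -> three pairs, BH across them
  set.seed(17)
  v <- c(stats::rnorm(8, 0), stats::rnorm(8, 1.5), stats::rnorm(8, 4))
  g <- rep(c("w", "h", "d"), each = 8)
  res3 <- pairwise_wilcoxon(v, g)
  expect_equal(nrow(res3), 3)
  expect_equal(res3$p_adjusted, hand_bh(res3$p_raw), tolerance = 1e-12)
  expect_true(all(res3$p_adjusted >= res3$p_raw - 1e-15))
  # enumeration oracle on one pair
  p_enum <- enum_wilcoxon_p(v[g == "d"][1:3], v[g == "h"][1:3])
  one <- pairwise_wilcoxon(c(v[g == "d"][1:3], v[g == "h"][1:3]),
                           rep(c("d", "h"), each = 3))
  expect_equal(one$p_raw, p_enum, tolerance = 1e-12)
})

test_that("BH-adjusted p-values are monotone in raw-p rank and capped at 1", {
  set.seed(29)
  for (rep in 1:10) {
    v <- stats::rnorm(40)
    g <- sample(letters[1:4], 40, replace = TRUE)
    res <- pairwise_wilcoxon(v, g)
    o <- order(res$p_raw)
    expect_true(all(diff(res$p_adjusted[o]) >= -1e-12))
    expect_true(all(res$p_adjusted <= 1))
  }
})

test_that("pooled t-test matches the hand computation", {
  res <- pooled_t_test(c(1, 2, 3), c(2, 3, 4))  # pooled SD = 1
  expect_equal(res$t, -1 / sqrt(2 / 3), tolerance = 1e-12)  # -1.2247
  expect_equal(res$df, 4)
  res0 <- pooled_t_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(res0$t, 0)
  expect_error(pooled_t_test(c(1, 1), c(1, 1)), "variance")
  expect_error(pooled_t_test(1, c(1, 2)), "n >= 2")
})

test_that("correlation screen: coding, pairwise completeness and invariances", {
  df <- make_raw_df(6)
  df$d34S <- NA_real_
  df$var_lin <- 2 * df$d15N + 1
  df$var_neg <- -df$d13C_measured
  df$var_const <- 5
  df$var_miss <- c(1, 2, NA, 4, 5, 6) * 2
  tab <- correct_d13c(apply_qc(as_sample_table(df))$table)

  res <- correlation_screen(tab, isotopes = c("d13C_cor", "d15N"),
                            variables = c("var_lin", "var_neg", "var_const",
                                          "var_miss", "sex"))
  get <- function(iso, v) res[res$isotope == iso & res$variable == v, ]
  expect_equal(get("d15N", "var_lin")$r, 1.0, tolerance = 1e-12)
  expect_equal(get("d13C_cor", "var_neg")$r, -1.0, tolerance = 1e-12)
  expect_identical(get("d15N", "var_const")$status, "undefined")
  expect_false(is.nan(get("d15N", "var_const")$r))

  # pairwise-complete: 5 pairs used, hand Pearson over those rows
  e <- get("d15N", "var_miss")
  ok <- !is.na(df$var_miss)
  expect_equal(e$n_pairs, sum(ok))
  expect_equal(e$r, stats::cor(tab$d15N[ok], df$var_miss[ok]),
               tolerance = 1e-12)

  # sex coded male=2 female=1: alternating m/f with increasing d15N
  expect_equal(get("d15N", "sex")$n_pairs, 6)

  # affine invariance (positive scale)
  df2 <- df; df2$var_lin <- 10 * df2$var_lin - 3
  tab2 <- correct_d13c(apply_qc(as_sample_table(df2))$table)
  res2 <- correlation_screen(tab2, isotopes = "d15N", variables = "var_lin")
  expect_equal(res2$r, 1.0, tolerance = 1e-12)

  # unclassified sex rows are excluded from the sex coding
  df3 <- make_raw_df(5); df3$sex <- c("m", "f", "", "m", "f")
  tab3 <- correct_d13c(apply_qc(as_sample_table(df3))$table)
  res3 <- correlation_screen(tab3, isotopes = "d15N", variables = "sex")
  expect_equal(res3$n_pairs, 4)
})

test_that("screens with too few complete pairs are flagged, not reported", {
  df <- make_raw_df(4)
  df$sparse <- c(1, 2, NA, NA)
  tab <- correct_d13c(apply_qc(as_sample_table(df))$table)
  res <- correlation_screen(tab, isotopes = "d15N", variables = "sparse")
  expect_identical(res$status, "too_few_pairs")
  expect_true(is.na(res$r))
})
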