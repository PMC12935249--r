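test_that("a valid CSV round-trips field-by-field to 12 significant digits", {
  df <- make_raw_df(5)
  df$pasture <- c(40.123456789012, 41, 42, 43, 44)  # covariate column
  tab <- as_sample_table(df, provenance = "unit test")
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_table(tab, path)
  tab2 <- read_sample_table(path)

  expect_s3_class(tab2, "sample_table")
  expect_equal(nrow(tab2), 5)
  expect_identical(tab2$sample_id, tab$sample_id)
  expect_identical(tab2$taxon, tab$taxon)
  expect_identical(tab2$sex, tab$sex)
  for (col in c("d13C_measured", "d15N", "d34S", "pctC", "pctN", "pctS",
                "year", "month", "pasture")) {
    expect_equal(tab2[[col]], tab[[col]], tolerance = 1e-12, label = col)
  }
  expect_true("pasture" %in% attr(tab2, "covariate_cols"))
})

test_that("schema errors name the missing column and bad rows are located", {
  df <- make_raw_df(3)
  path <- withr::local_tempfile(fileext = ".csv")

  utils::write.csv(df[, setdiff(names(df), "d15N")], path, row.names = FALSE)
  expect_error(read_sample_table(path), "d15N")

  df_bad <- df
  df_bad$d13C_measured <- as.character(df_bad$d13C_measured)
  df_bad$d13C_measured[2] <- "not-a-number"
  utils::write.csv(df_bad, path, row.names = FALSE)
  expect_error(read_sample_table(path), "row\\(s\\) 2")

  df_dup <- df
  df_dup$sample_id <- c("A", "A", "B")
  expect_error(as_sample_table(df_dup), "not unique")

  df_oob <- df
  df_oob$d15N[1] <- 35  # outside sanity bounds -> validation error, not drop
  expect_error(as_sample_table(df_oob), "d15N")
})

test_that("enum and region values are normalised case-insensitively", {
  df <- make_raw_df(3)
  df$taxon <- c("Wildcat", "Domestic Cat", "HYBRID")
  df$sex <- c("F", "Male", "")
  df$region <- c(" Markgräflerland ", "markgraeflerland", "Taunus")
  tab <- as_sample_table(df)
  expect_identical(tab$taxon, c("wildcat", "domestic_cat", "hybrid"))
  expect_identical(tab$sex, c("female", "male", "unknown"))
  expect_identical(tab$region[1], "Markgraeflerland")
  expect_identical(tab$region[1], tab$region[2])
  expect_error(as_sample_table({
    d <- make_raw_df(1); d$taxon <- "lynx"; d
  }), "taxon")
})

test_that("write_report emits a CSV that re-reads identically plus stable JSON", {
  tab <- as_sample_table(make_raw_df(4))
  metrics <- data.frame(group = c("a", "b"),
                        TA = c(16.912345678901234, 25.8),
                        SEAc = c(5.7, 12.8))
  path <- file.path(withr::local_tempdir(), "metrics.csv")
  out <- write_report(tab, metrics, path, seed = 42L)
  back <- utils::read.csv(path)
  expect_equal(back$TA, metrics$TA, tolerance = 1e-12)
  expect_equal(back$SEAc, metrics$SEAc, tolerance = 1e-12)

  meta <- jsonlite::read_json(out$json)
  expect_equal(meta$seed, 42L)
  expect_equal(meta$counts$n_samples, 4L)

  # degenerate case: empty report still yields valid JSON with counts
  out2 <- write_report(tab, metrics[0, ], file.path(dirname(path), "empty.csv"))
  meta2 <- jsonlite::read_json(out2$json)
  expect_equal(meta2$counts$n_rows_report, 0L)

  # byte-identical apart from the timestamp for a repeated seeded run
  out3 <- write_report(tab, metrics, file.path(dirname(path), "again.csv"),
                       seed = 42L)
  strip_ts <- function(p) {
    l <- readLines(p)
    l[!grepl("timestamp", l)]
  }
  expect_identical(strip_ts(out$json), strip_ts(out3$json))
  expect_identical(readLines(path), readLines(file.path(dirname(path), "again.csv")))
})
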