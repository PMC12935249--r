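# Reading, validation and writing of per-individual hair sample tables.

# Columns every table must provide. Everything else is optional or carried
# along as a covariate column.
MANDATORY_COLS <- c("sample_id", "taxon", "d13C_measured", "d15N", "pctC", "pctN")

OPTIONAL_COLS <- c(
  "region", "case_study", "year", "month", "sex", "d34S", "pctS",
  "d13C_cor", "weight", "body_length", "hindfoot_length", "age_class"
)

NUMERIC_COLS <- c(
  "d13C_measured", "d15N", "d34S", "pctC", "pctN", "pctS", "d13C_cor",
  "year", "month", "case_study", "weight", "body_length", "hindfoot_length"
)

TAXON_LEVELS <- c("wildcat", "domestic_cat", "hybrid")
SEX_LEVELS <- c("male", "female", "unknown")

# Canonical region spellings after diacritic folding.
KNOWN_REGIONS <- c(
  "Taunus", "Markgraeflerland", "Hainich", "East Thuringia",
  "Harz Foreland", "Thuringian Basin", "Thuringian Forest", "Thuringia"
)

#' Fold German diacritics and trim whitespace in region names
#'
#' Region labels are matched after trimming and folding of diacritics
#' (\code{"Markgräflerland"} and \code{"Markgraeflerland"} are the same
#' region), so joins against covariate tables are robust to the encoding of
#' the source file.
#'
#' @param x character vector of region names.
#' @return character vector with diacritics folded (ae/oe/ue/ss) and
#'   surrounding whitespace removed; empty strings become `NA`.
#' @export
fold_region <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("ä", "ae", x)
  x <- gsub("ö", "oe", x)
  x <- gsub("ü", "ue", x)
  x <- gsub("Ä", "Ae", x)
  x <- gsub("Ö", "Oe", x)
  x <- gsub("Ü", "Ue", x)
  x <- gsub("ß", "ss", x)
  x[x == "" | toupper(x) == "NA"] <- NA_character_
  # snap to canonical capitalisation when a case-insensitive match exists
  idx <- match(tolower(gsub("[_ ]+", " ", x)),
               tolower(KNOWN_REGIONS))
  x[!is.na(idx)] <- KNOWN_REGIONS[idx[!is.na(idx)]]
  x
}

normalize_taxon <- function(x) {
  x0 <- tolower(trimws(as.character(x)))
  x0 <- gsub("[_ ]+", " ", x0)
  out <- rep(NA_character_, length(x0))
  out[x0 %in% c("wildcat", "wild cat", "felis silvestris", "wc")] <- "wildcat"
  out[x0 %in% c("domestic cat", "domesticcat", "domestic", "house cat",
                "housecat", "felis catus", "dc")] <- "domestic_cat"
  out[x0 %in% c("hybrid", "hyb")] <- "hybrid"
  bad <- !is.na(x0) & x0 != "" & x0 != "na" & is.na(out)
  if (any(bad)) {
    stop("unrecognised taxon value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

normalize_sex <- function(x) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x0))
  out[x0 %in% c("m", "male")] <- "male"
  out[x0 %in% c("f", "female", "w")] <- "female"
  out[is.na(x0) | x0 %in% c("", "na", "u", "unknown", "?")] <- "unknown"
  bad <- !(x0 %in% c("m", "male", "f", "female", "w", "", "na", "u",
                     "unknown", "?")) & !is.na(x0)
  if (any(bad)) {
    stop("unrecognised sex value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

parse_numeric_col <- function(x, col) {
  x0 <- trimws(as.character(x))
  x0[x0 == "" | toupper(x0) == "NA"] <- NA
  suppressWarnings(v <- as.numeric(x0))
  bad <- which(!is.na(x0) & is.na(v))
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable numeric cell in row(s) %s",
                 col, paste(bad, collapse = ", ")), call. = FALSE)
  }
  v
}

#' Construct a validated sample table
#'
#' A `sample_table` is a plain `data.frame` (one row per individual) with a
#' validated schema: unique `sample_id`, normalised `taxon` / `sex` factors
#' (stored as character), folded `region` names and numeric isotope and
#' elemental columns inside sanity bounds. Any column not in the core schema
#' is preserved as a covariate column and recorded in
#' `attr(x, "covariate_cols")`.
#'
#' @param df data.frame of raw samples.
#' @param provenance free-text note on where the table came from.
#' @return a `sample_table` (data.frame subclass).
#' @export
as_sample_table <- function(df, provenance = "unspecified") {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) stop("sample table is empty", call. = FALSE)
  missing_cols <- setdiff(MANDATORY_COLS, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  for (col in intersect(NUMERIC_COLS, names(df))) {
    df[[col]] <- parse_numeric_col(df[[col]], col)
  }
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id)) {
    stop("sample_id values are not unique: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  df$taxon <- normalize_taxon(df$taxon)
  if (anyNA(df$taxon)) {
    stop("missing taxon in row(s) ", paste(which(is.na(df$taxon)), collapse = ", "),
         call. = FALSE)
  }
  df$sex <- if ("sex" %in% names(df)) normalize_sex(df$sex) else "unknown"
  df$region <- if ("region" %in% names(df)) fold_region(df$region) else NA_character_
  if (!"case_study" %in% names(df)) df$case_study <- NA_real_
  for (col in setdiff(OPTIONAL_COLS, names(df))) {
    df[[col]] <- if (col == "age_class") NA_character_ else NA_real_
  }

  check_bounds <- function(col, lo, hi) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad)) {
      stop(sprintf("validation error: %s outside [%g, %g] for sample(s) %s",
                   col, lo, hi, paste(df$sample_id[bad], collapse = ", ")),
           call. = FALSE)
    }
  }
  check_bounds("d13C_measured", -40, 0)
  check_bounds("d15N", -10, 20)
  check_bounds("d34S", -20, 25)
  check_bounds("pctC", 0, 100)
  check_bounds("pctN", 0, 100)
  check_bounds("pctS", 0, 100)
  check_bounds("month", 1, 12)

  core <- c(MANDATORY_COLS, OPTIONAL_COLS)
  cov_cols <- setdiff(names(df), core)
  # covariate columns: parse as numeric when every non-missing cell parses,
  # otherwise keep as character
  for (col in cov_cols) {
    if (!is.character(df[[col]])) next
    x0 <- trimws(df[[col]])
    x0[x0 == "" | toupper(x0) == "NA"] <- NA
    suppressWarnings(v <- as.numeric(x0))
    if (!any(!is.na(x0) & is.na(v))) df[[col]] <- v
  }
  df <- df[, c(intersect(core, names(df)), cov_cols), drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            class = c("sample_table", "data.frame"),
            provenance = provenance,
            covariate_cols = cov_cols)
}

#' Read a per-individual sample table from CSV/TSV
#'
#' Reads a UTF-8 delimited file with a header row and maps every row to a
#' validated sample record. Enum fields are normalised case-insensitively
#' ("Domestic Cat" -> `domestic_cat`, "F" -> `female`), region names are
#' diacritic-folded, and unknown columns are preserved as covariates. Missing
#' values may be encoded as empty cells or "NA". The reader never silently
#' drops rows: an unparseable cell or an out-of-bounds value raises an error
#' naming the column and row.
#'
#' @param path path to the file.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return a [as_sample_table()] object.
#' @export
read_sample_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("no data rows in ", path, call. = FALSE)
  as_sample_table(raw, provenance = normalizePath(path))
}

#' Write a sample table to CSV
#'
#' Numeric cells are written with 15 significant digits so that
#' `read_sample_table(write_sample_table(x))` round-trips values to at least
#' 12 significant digits.
#'
#' @param table a `sample_table`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  df <- as.data.frame(table)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      df[[col]] <- ifelse(is.na(df[[col]]), "",
                          format(df[[col]], digits = 15, trim = TRUE,
                                 scientific = FALSE))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a tabular report plus a JSON run-metadata sidecar
#'
#' Writes `metrics` (any data.frame-like report, e.g. a table of Layman
#' metrics or trend fits) as CSV at `path`, and a JSON sidecar
#' (`<path with .json extension>`) carrying run metadata: sample counts by
#' taxon, provenance, software version, optional config echo and seed, and a
#' timestamp. Re-reading the CSV reproduces the numeric content to at least
#' 12 significant digits. Apart from the `timestamp` field the JSON of a
#' seeded run is byte-stable across repeat runs.
#'
#' @param table the `sample_table` the report was computed from (may be `NULL`).
#' @param metrics a data.frame (or coercible) of results; may have zero rows.
#' @param path destination CSV path; the JSON sidecar swaps the extension.
#' @param config optional config object echoed into the JSON.
#' @param seed optional integer seed echoed into the JSON.
#' @return invisible list with the two paths written.
#' @export
write_report <- function(table, metrics, path, config = NULL, seed = NULL) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  metrics <- as.data.frame(metrics, stringsAsFactors = FALSE)
  out <- metrics
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           format(out[[col]], digits = 15, trim = TRUE,
                                  scientific = FALSE))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")

  meta <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    software = list(package = "felisotope",
                    version = as.character(utils::packageVersion("felisotope")),
                    r_version = paste(R.version$major, R.version$minor, sep = ".")),
    counts = list(
      n_rows_report = nrow(metrics),
      n_samples = if (is.null(table)) 0L else nrow(table),
      by_taxon = if (is.null(table)) NULL else as.list(table(table$taxon))
    ),
    provenance = if (is.null(table)) NULL else attr(table, "provenance"),
    seed = seed,
    config = config
  )
  json_path <- sub("\\.[A-Za-z0-9]+$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(list(csv = path, json = json_path))
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$taxon)), table(x$taxon)),
                    collapse = ", ")))
  cat("provenance:", attr(x, "provenance"), "\n")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
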