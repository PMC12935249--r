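# Elemental QC and delta-13C corrections.
#
# Atomic ratios follow the standard mass-to-atom conversion with atomic
# masses C 12.007, N 14.011, S 32.060. The retention rule is: atomic C/N in
# [3.0, 4.05], %C <= 50, %N <= 20, and a regional assignment present. C/S and
# N/S windows are advisory (flagged, never excluded) by default.

ATOMIC_MASS_C <- 12.007
ATOMIC_MASS_N <- 14.011
ATOMIC_MASS_S <- 32.060

#' Atomic elemental ratios from mass percentages
#'
#' Converts mass-percent elemental contents to atomic ratios:
#' \deqn{C/N = (\%C \times 14.011) / (\%N \times 12.007)}
#' \deqn{C/S = (\%C \times 32.060) / (\%S \times 12.007)}
#' \deqn{N/S = (\%N \times 32.060) / (\%S \times 14.011)}
#' Keratin integrity is judged on C/N; C/S and N/S serve as advisory checks
#' when sulfur was measured.
#'
#' @param pctC,pctN mass percent carbon / nitrogen (> 0). Vectorised.
#' @param pctS mass percent sulfur, or `NA` when sulfur was not measured.
#' @return a data.frame with columns `c_n`, `c_s`, `n_s` (the latter two `NA`
#'   when `pctS` is absent).
#' @export
atomic_ratios <- function(pctC, pctN, pctS = NA_real_) {
  n <- max(length(pctC), length(pctN), length(pctS))
  pctC <- rep_len(pctC, n); pctN <- rep_len(pctN, n); pctS <- rep_len(pctS, n)
  if (any(!is.na(pctC) & pctC <= 0) || any(!is.na(pctN) & pctN <= 0)) {
    stop("pctC and pctN must be strictly positive", call. = FALSE)
  }
  if (any(!is.na(pctS) & pctS <= 0)) {
    stop("pctS must be strictly positive when supplied", call. = FALSE)
  }
  c_n <- (pctC * ATOMIC_MASS_N) / (pctN * ATOMIC_MASS_C)
  c_s <- (pctC * ATOMIC_MASS_S) / (pctS * ATOMIC_MASS_C)
  n_s <- (pctN * ATOMIC_MASS_S) / (pctS * ATOMIC_MASS_N)
  data.frame(c_n = c_n, c_s = c_s, n_s = n_s)
}

#' Quality-control configuration
#'
#' Defaults reproduce the analysis rule set: exclude when atomic C/N falls
#' outside \[3.0, 4.05\], %C > 50 (strictly; 50.0 is retained), %N > 20, or
#' the regional assignment is missing. The narrower general keratin criterion
#' (C/N 2.9-3.6) can be requested via `cn_min`/`cn_max`. The C/S (300-900)
#' and N/S (100-300) windows only flag samples.
#'
#' @param cn_min,cn_max accepted atomic C/N window.
#' @param pctC_max,pctN_max maximum retained mass percents (exclusive above).
#' @param cs_range,ns_range advisory atomic ratio windows (length-2).
#' @param require_region exclude samples without a regional assignment?
#' @return a `qc_config` list.
#' @export
qc_config <- function(cn_min = 3.0, cn_max = 4.05, pctC_max = 50,
                      pctN_max = 20, cs_range = c(300, 900),
                      ns_range = c(100, 300), require_region = TRUE) {
  stopifnot(cn_min < cn_max, cs_range[1] < cs_range[2],
            ns_range[1] < ns_range[2])
  structure(list(cn_min = cn_min, cn_max = cn_max, pctC_max = pctC_max,
                 pctN_max = pctN_max, cs_range = cs_range,
                 ns_range = ns_range, require_region = require_region),
            class = "qc_config")
}

#' Apply elemental quality control to a sample table
#'
#' A sample is retained iff `cn_min <= C/N <= cn_max`, `pctC <= pctC_max`,
#' `pctN <= pctN_max` and (when `require_region`) a region is assigned. The
#' order of retained samples is preserved and every excluded sample carries
#' at least one machine-readable reason code
#' (`cn_out_of_range`, `pctC_high`, `pctN_high`, `missing_region`).
#' Advisory C/S and N/S flags are recorded but never exclude. QC is
#' idempotent: re-applying it to the retained table changes nothing.
#'
#' @param table a `sample_table` with `pctC` and `pctN` for every sample.
#' @param config a [qc_config()].
#' @return list with `table` (retained `sample_table`) and `report`
#'   (a `qc_report`: per-sample decisions plus totals).
#' @export
apply_qc <- function(table, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  if (!inherits(table, "sample_table")) table <- as_sample_table(table)
  if (nrow(table) == 0L) stop("empty sample table", call. = FALSE)
  if (anyNA(table$pctC) || anyNA(table$pctN)) {
    stop("pctC/pctN required for every sample before QC", call. = FALSE)
  }
  rat <- atomic_ratios(table$pctC, table$pctN, table$pctS)

  # boundaries are inclusive; the epsilon keeps values sitting exactly on a
  # threshold from being excluded by floating-point round-off
  eps <- 1e-9
  fail_cn <- rat$c_n < config$cn_min - eps | rat$c_n > config$cn_max + eps
  fail_c <- table$pctC > config$pctC_max + eps
  fail_n <- table$pctN > config$pctN_max + eps
  fail_region <- config$require_region & is.na(table$region)

  flag_cs <- !is.na(rat$c_s) &
    (rat$c_s < config$cs_range[1] | rat$c_s > config$cs_range[2])
  flag_ns <- !is.na(rat$n_s) &
    (rat$n_s < config$ns_range[1] | rat$n_s > config$ns_range[2])

  retained <- !(fail_cn | fail_c | fail_n | fail_region)
  reasons <- vapply(seq_len(nrow(table)), function(i) {
    r <- c(if (fail_cn[i]) "cn_out_of_range", if (fail_c[i]) "pctC_high",
           if (fail_n[i]) "pctN_high", if (fail_region[i]) "missing_region")
    paste(r, collapse = ";")
  }, character(1))
  advisory <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(if (flag_cs[i]) "cs_out_of_range", if (flag_ns[i]) "ns_out_of_range"),
          collapse = ";")
  }, character(1))

  per_sample <- data.frame(
    sample_id = table$sample_id, c_n = rat$c_n, c_s = rat$c_s, n_s = rat$n_s,
    retained = retained, reasons = reasons, advisory_flags = advisory,
    stringsAsFactors = FALSE
  )
  totals <- list(
    n_input = nrow(table),
    n_retained = sum(retained),
    n_excluded = sum(!retained),
    n_excluded_by_reason = c(
      cn_out_of_range = sum(fail_cn), pctC_high = sum(fail_c),
      pctN_high = sum(fail_n), missing_region = sum(fail_region)
    )
  )
  report <- structure(list(per_sample = per_sample, totals = totals,
                           config = config),
                      class = "qc_report")

  kept <- as.data.frame(table)[retained, , drop = FALSE]
  rownames(kept) <- NULL
  kept <- structure(kept, class = c("sample_table", "data.frame"),
                    provenance = attr(table, "provenance"),
                    covariate_cols = attr(table, "covariate_cols"))
  list(table = kept, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<qc_report> %d in, %d retained, %d excluded\n",
              t$n_input, t$n_retained, t$n_excluded))
  print(t$n_excluded_by_reason)
  invisible(x)
}

#' Lipid correction of measured delta-13C
#'
#' Bulk hair contains 13C-depleted lipids; when no chemical lipid extraction
#' was performed the measured value is adjusted post hoc with the affine map
#' \deqn{\delta^{13}C_{lipid-free} = 0.982 \times \delta^{13}C_{measured} - 0.028}
#' The map is strictly increasing, so it preserves sample ordering.
#'
#' @param d13C_measured per-mil values vs V-PDB. Vectorised.
#' @return lipid-corrected per-mil values.
#' @export
lipid_correct <- function(d13C_measured) {
  0.982 * d13C_measured - 0.028
}

#' Atmospheric delta-13C model for the Suess correction
#'
#' The Suess effect is the fossil-fuel-driven decline of atmospheric
#' \eqn{\delta^{13}}C; tissue values of different collection years are only
#' comparable after shifting each to a common (pre-industrial) baseline. The
#' model is an annual atmospheric series plus a baseline value. The packaged
#' default series (`atm_d13c_synthetic.csv`, 1850-2022) is a synthetic
#' reconstruction interpolated through published-magnitude anchor values of
#' the global atmospheric record and should be replaced by a measured series
#' (e.g. a flask-record annual mean) for absolute work; corrections are pure
#' per-year shifts either way.
#'
#' @param series data.frame with columns `year`, `d13C_atm`, or a path to a
#'   two-column CSV; `NULL` loads the packaged synthetic series.
#' @param baseline pre-industrial atmospheric \eqn{\delta^{13}}C (per-mil).
#' @return a `suess_model` list with `atm_series` (named numeric vector,
#'   names = years) and `baseline`.
#' @export
suess_model <- function(series = NULL, baseline = -6.4) {
  if (is.null(series)) {
    series <- utils::read.csv(system.file("extdata", "atm_d13c_synthetic.csv",
                                          package = "felisotope"))
  } else if (is.character(series)) {
    series <- utils::read.csv(series)
  }
  stopifnot(all(c("year", "d13C_atm") %in% names(series)))
  if (any(series$d13C_atm < -10 | series$d13C_atm > -5)) {
    stop("atmospheric delta-13C series outside plausible range [-10, -5]",
         call. = FALSE)
  }
  if (anyDuplicated(series$year)) stop("duplicated years in series", call. = FALSE)
  atm <- stats::setNames(series$d13C_atm, series$year)
  structure(list(atm_series = atm, baseline = baseline), class = "suess_model")
}

#' Suess correction of lipid-free delta-13C
#'
#' Shifts each value by the atmospheric depletion of its collection year
#' relative to the pre-industrial baseline:
#' \deqn{\delta^{13}C_{cor} = \delta^{13}C_{lipid-free} - (\delta^{13}C_{atm}(year) - baseline)}
#' A pure per-year shift: within-year differences are preserved exactly, and
#' under a monotonically declining atmospheric series later years receive
#' larger positive shifts.
#'
#' @param d13C_lipid_free per-mil values. Vectorised (with `year`).
#' @param year collection year(s); every year must be covered by the series
#'   (no extrapolation).
#' @param model a [suess_model()].
#' @return Suess-corrected per-mil values.
#' @export
suess_correct <- function(d13C_lipid_free, year, model = suess_model()) {
  stopifnot(inherits(model, "suess_model"))
  n <- max(length(d13C_lipid_free), length(year))
  d13C_lipid_free <- rep_len(d13C_lipid_free, n)
  year <- rep_len(year, n)
  atm <- model$atm_series[as.character(year)]
  missing_years <- unique(year[is.na(atm) & !is.na(year)])
  if (length(missing_years)) {
    stop("atmospheric series does not cover year(s): ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  d13C_lipid_free - (unname(atm) - model$baseline)
}

#' Apply lipid then Suess correction to a sample table
#'
#' Adds/overwrites a `d13C_cor` column: lipid correction first, then the
#' Suess shift using each sample's collection year. Samples without a year
#' receive only the lipid correction and are flagged in the returned
#' attribute `suess_uncorrected` (their ids).
#'
#' @param table a `sample_table`.
#' @param model a [suess_model()].
#' @return the table with `d13C_cor` filled in.
#' @export
correct_d13c <- function(table, model = suess_model()) {
  lf <- lipid_correct(table$d13C_measured)
  cor <- lf
  has_year <- !is.na(table$year)
  if (any(has_year)) {
    cor[has_year] <- suess_correct(lf[has_year], table$year[has_year], model)
  }
  table$d13C_cor <- cor
  attr(table, "suess_uncorrected") <- table$sample_id[!has_year]
  table
}
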