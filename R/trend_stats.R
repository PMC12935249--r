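# Seasonal assignment, temporal trend fits, pairwise rank-sum tests,
# pooled t-tests and the Pearson correlation screen.

#' Assign hair samples to a growth season from the collection month
#'
#' Cats moult in spring and autumn, and hair integrates diet over the months
#' it grew. Samples collected December-April therefore carry the signal of
#' hair grown during the preceding spring-summer ("summer_grown"), while
#' samples collected May-November carry autumn-winter growth
#' ("winter_grown"). A missing month yields "unclassified". The three labels
#' partition the months: every month maps to exactly one label.
#'
#' @param month integer vector in 1..12 (or `NA`).
#' @return character vector of season labels.
#' @export
assign_season <- function(month) {
  out <- rep("unclassified", length(month))
  known <- !is.na(month)
  if (any(known & (month < 1 | month > 12 | month != floor(month)))) {
    stop("month must be an integer in 1..12", call. = FALSE)
  }
  out[known & month %in% c(12, 1, 2, 3, 4)] <- "summer_grown"
  out[known & month %in% 5:11] <- "winter_grown"
  out
}

#' Temporal trend fit (ordinary or Huber-robust least squares)
#'
#' Fits `values ~ years` by ordinary least squares (`method = "ols"`) or by
#' Huber M-estimation (`method = "huber"`, tuning constant 1.345 times the
#' robust scale, iteratively reweighted, convergence when the coefficient
#' change drops below 1e-8 or after 50 iterations). The robust fit
#' down-weights gross outliers; with small residual spread (no weight below
#' 1) it coincides with OLS. `r_squared` always reports the OLS coefficient
#' of determination so the two fits can be read side by side; the slope
#' p-value is the OLS t-test for `"ols"` and a normal-approximation Wald test
#' for `"huber"`.
#'
#' @param years integer vector (>= 2 distinct values).
#' @param values per-mil values, same length, n >= 3.
#' @param method `"ols"` or `"huber"`.
#' @return a `trend_fit` list: `slope` (per-mil per year), `intercept`,
#'   `r_squared`, `p_value`, `n`, `method`, and `converged` (`FALSE` when the
#'   robust reweighting hit the iteration cap; the last iterate is still
#'   returned).
#' @export
fit_trend <- function(years, values, method = c("ols", "huber")) {
  method <- match.arg(method)
  ok <- is.finite(years) & is.finite(values)
  years <- years[ok]; values <- values[ok]
  n <- length(years)
  if (n < 3) stop("need n >= 3 for a trend fit", call. = FALSE)
  if (length(unique(years)) < 2) {
    stop("all years identical: no temporal trend estimable", call. = FALSE)
  }
  ols <- stats::lm(values ~ years)
  s_ols <- suppressWarnings(summary(ols))  # exact fits warn harmlessly
  r2 <- s_ols$r.squared
  converged <- TRUE
  if (method == "ols") {
    slope <- unname(stats::coef(ols)[2])
    intercept <- unname(stats::coef(ols)[1])
    p <- s_ols$coefficients["years", "Pr(>|t|)"]
  } else {
    rfit <- withCallingHandlers(
      MASS::rlm(values ~ years, psi = MASS::psi.huber, k = 1.345,
                maxit = 50, acc = 1e-8),
      warning = function(w) {
        if (grepl("failed to converge", conditionMessage(w))) {
          converged <<- FALSE
          invokeRestart("muffleWarning")
        }
      })
    slope <- unname(stats::coef(rfit)[2])
    intercept <- unname(stats::coef(rfit)[1])
    se <- suppressWarnings(summary(rfit))$coefficients["years", "Std. Error"]
    p <- 2 * stats::pnorm(-abs(slope / se))
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 p_value = p, n = n, method = method, converged = converged),
            class = "trend_fit")
}

#' Pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg correction
#'
#' Two-sided rank-sum test for every unordered pair of groups; p-values are
#' Benjamini-Hochberg adjusted across all pairs (call once per isotope). The
#' exact null distribution is used when both groups have n <= 10 and there
#' are no ties; otherwise the normal approximation with continuity and tie
#' correction. The reported statistic is the rank-sum of the first group of
#' the pair (i.e. the Mann-Whitney U plus n1(n1+1)/2).
#'
#' @param values numeric vector.
#' @param groups vector of group labels, same length; >= 2 groups, each
#'   non-empty.
#' @return data.frame with one row per pair: `group_a`, `group_b`, `n_a`,
#'   `n_b`, `statistic`, `p_raw`, `p_adjusted`, `exact`.
#' @export
pairwise_wilcoxon <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  split_vals <- split(values, groups)
  if (length(split_vals) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(split_vals) == 0)) stop("empty group", call. = FALSE)
  pairs <- utils::combn(names(split_vals), 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- split_vals[[pairs[1, j]]]
    b <- split_vals[[pairs[2, j]]]
    no_ties <- !anyDuplicated(c(a, b))
    exact <- length(a) <= 10 && length(b) <= 10 && no_ties
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                         alternative = "two.sided"))
    data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
               n_a = length(a), n_b = length(b),
               statistic = unname(wt$statistic) + length(a) * (length(a) + 1) / 2,
               p_raw = wt$p.value, exact = exact,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = "BH")
  res[, c("group_a", "group_b", "n_a", "n_b", "statistic",
          "p_raw", "p_adjusted", "exact")]
}

#' Pooled-variance two-sample t-test
#'
#' Student's t-test with pooled variance: df = n_a + n_b - 2, two-sided
#' p-value. (The equal-variance form, not Welch's.)
#'
#' @param a,b numeric vectors, each n >= 2; the pooled variance must be > 0.
#' @return list with `t`, `df`, `p`, and the group means.
#' @export
pooled_t_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group", call. = FALSE)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b))
}

#' Pearson correlation screen of isotopes against covariates
#'
#' Pearson r for every isotope x variable pair over pairwise-complete
#' observations. `sex` is coded numerically inside the screen only
#' (males = 2, females = 1, unknown excluded); everywhere else in the
#' package sex stays categorical. Entries with fewer than 3 complete pairs
#' are flagged `"too_few_pairs"` and a zero-variance variable yields
#' `"undefined"`, never `NaN`. The screen is invariant to affine rescaling
#' of either variable (up to the sign of the scale factor).
#'
#' @param table a `sample_table` (typically already subset, e.g. to
#'   Thuringian wildcats).
#' @param isotopes character vector of isotope column names.
#' @param variables character vector of numeric columns (covariates,
#'   morphometrics, `"sex"`, `"year"`, ...).
#' @return data.frame with `isotope`, `variable`, `r`, `n_pairs`, `status`
#'   (`"ok"`, `"too_few_pairs"` or `"undefined"`).
#' @export
correlation_screen <- function(table,
                               isotopes = c("d13C_cor", "d15N", "d34S"),
                               variables) {
  df <- as.data.frame(table)
  get_var <- function(v) {
    if (v == "sex") {
      s <- df$sex
      out <- ifelse(s == "male", 2, ifelse(s == "female", 1, NA_real_))
      return(out)
    }
    if (!v %in% names(df)) stop("unknown variable: ", v, call. = FALSE)
    x <- df[[v]]
    if (!is.numeric(x)) stop("variable not numeric: ", v, call. = FALSE)
    x
  }
  grid <- expand.grid(isotope = isotopes, variable = variables,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    iso <- grid$isotope[i]; v <- grid$variable[i]
    if (!iso %in% names(df)) stop("unknown isotope column: ", iso, call. = FALSE)
    x <- df[[iso]]; y <- get_var(v)
    ok <- is.finite(x) & is.finite(y)
    n_pairs <- sum(ok)
    if (n_pairs < 3) {
      r <- NA_real_; status <- "too_few_pairs"
    } else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      r <- NA_real_; status <- "undefined"
    } else {
      r <- stats::cor(x[ok], y[ok]); status <- "ok"
    }
    data.frame(isotope = iso, variable = v, r = r, n_pairs = n_pairs,
               status = status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
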