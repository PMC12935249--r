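# Synthetic sample-table generator with known ground truth.
#
# Emulates the structure of the study table: per-group trivariate-normal
# isotope values (d13C_cor, d15N, d34S), keratin-like elemental composition
# with an optional contamination fraction that fails QC, collection dates,
# sex-correlated morphometrics, and land-use / climate covariates with
# configurable linear effects on the isotopes. All contrasts (year trend,
# sex, season, covariates) are applied as zero-mean deviations, so a group's
# expected isotope mean stays exactly `mu`.

ISOTOPES <- c("d13C_cor", "d15N", "d34S")

zero_effect <- function() stats::setNames(numeric(3), ISOTOPES)

as_effect <- function(x) {
  out <- zero_effect()
  if (is.null(x)) return(out)
  if (is.null(names(x))) {
    stopifnot(length(x) == 3)
    out[] <- x
  } else {
    stopifnot(all(names(x) %in% ISOTOPES))
    out[names(x)] <- x
  }
  out
}

#' Specification of one synthetic group (taxon x region)
#'
#' @param taxon one of `"wildcat"`, `"domestic_cat"`, `"hybrid"`.
#' @param region region name (folded via [fold_region()]).
#' @param case_study 1 or 2.
#' @param n number of (clean) individuals.
#' @param mu length-3 isotope means (d13C_cor, d15N, d34S, per-mil).
#' @param sigma 3x3 covariance, or length-3 SDs (expanded to a diagonal
#'   covariance; isotope axes are independent by default).
#' @param elemental list of elemental means/SDs: `pctC` (default c(45, 2)),
#'   `pctN` (c(14.5, 1)), `pctS` (c(0.2, 0.03)), and `rho` (default 0.95),
#'   the pctC-pctN correlation that encodes keratin's stoichiometric
#'   coupling (independent marginals would spread atomic C/N far beyond the
#'   biologically possible range).
#' @param qc_fail_rate probability that a row is turned into a contaminant
#'   failing QC (inflated %C > 50 or depressed %N driving C/N > 4.05).
#' @param sex_ratio probability that an individual is male.
#' @param year_range optional length-2 override of the scenario-wide
#'   collection-year range (use `c(y, y)` for a single-year campaign).
#' @param months optional vector of admissible collection months.
#' @param year_effect optional named per-isotope slope (per-mil / year)
#'   overriding the scenario-wide `year_effect` for this group.
#' @return a `group_spec` list.
#' @export
group_spec <- function(taxon, region, case_study, n, mu, sigma,
                       elemental = list(), qc_fail_rate = 0, sex_ratio = 0.5,
                       year_range = NULL, months = NULL, year_effect = NULL) {
  taxon <- normalize_taxon(taxon)
  if (length(sigma) == 3 && is.null(dim(sigma))) sigma <- diag(sigma^2)
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("sigma is not positive definite", call. = FALSE)
  stopifnot(n >= 1, length(mu) == 3, qc_fail_rate >= 0, qc_fail_rate <= 1,
            sex_ratio >= 0, sex_ratio <= 1)
  el <- utils::modifyList(
    list(pctC = c(45, 2), pctN = c(14.5, 1), pctS = c(0.2, 0.03), rho = 0.95),
    elemental)
  structure(list(taxon = taxon, region = fold_region(region),
                 case_study = case_study, n = as.integer(n),
                 mu = as.numeric(mu), sigma = sigma, elemental = el,
                 qc_fail_rate = qc_fail_rate, sex_ratio = sex_ratio,
                 year_range = year_range, months = months,
                 year_effect = if (is.null(year_effect)) NULL
                               else as_effect(year_effect)),
            class = "group_spec")
}

#' Scenario-wide covariate / temporal / sex structure
#'
#' @param year_range collection-year span (calendar years).
#' @param month_probs sampling weights of collection months 1..12.
#' @param year_effect named per-isotope slope (per-mil / year), applied as
#'   `effect * (year - midpoint(year_range))` (groups may override).
#' @param covariates named list; each entry is a list with `mean`, `sd`,
#'   optional `year_slope` (drift of the covariate itself), and `effect`
#'   (named per-isotope slope per covariate unit, applied to the covariate's
#'   deviation from its static mean).
#' @param sex_effect named per-isotope male-vs-female contrast (per-mil);
#'   applied as a zero-mean deviation given the group's sex ratio.
#' @param seasonal_d13C_summer summer-grown minus winter-grown d13C contrast
#'   (per-mil), applied as a zero-mean deviation given the month weights.
#' @param morpho sex-specific normal models (mean, sd) for `weight` (kg),
#'   `body_length` (mm), `hindfoot_length` (mm); generated for case-study-2
#'   individuals (carcass collections), absent for hair-trap samples.
#' @return a `covariate_spec` list.
#' @export
covariate_spec <- function(year_range = c(1995, 2021),
                           month_probs = rep(1 / 12, 12),
                           year_effect = NULL,
                           covariates = list(),
                           sex_effect = NULL,
                           seasonal_d13C_summer = 0,
                           morpho = list(
                             male = list(weight = c(5.0, 0.6),
                                         body_length = c(590, 35),
                                         hindfoot_length = c(135, 7)),
                             female = list(weight = c(3.7, 0.45),
                                           body_length = c(540, 30),
                                           hindfoot_length = c(125, 6)))) {
  stopifnot(year_range[1] <= year_range[2], length(month_probs) == 12)
  covariates <- lapply(covariates, function(cv) {
    utils::modifyList(list(year_slope = 0, effect = NULL), cv)
  })
  structure(list(year_range = year_range,
                 month_probs = month_probs / sum(month_probs),
                 year_effect = as_effect(year_effect),
                 covariates = covariates,
                 sex_effect = as_effect(sex_effect),
                 seasonal_d13C_summer = seasonal_d13C_summer,
                 morpho = morpho),
            class = "covariate_spec")
}

#' Full generative scenario
#'
#' @param groups list of [group_spec()]s.
#' @param covariates a [covariate_spec()].
#' @param seed integer seed (mandatory; all randomness derives from it).
#' @param contaminants list `n_cn` / `n_pctC`: numbers of extra rows appended
#'   (round-robin across groups) whose elemental composition deterministically
#'   fails QC via an out-of-window atomic C/N ratio or excessive %C.
#' @param suess [suess_model()] used to back-transform the generated
#'   (corrected-space) d13C truth into `d13C_measured`, so that the pipeline's
#'   lipid + Suess corrections exactly recover the generated values.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(groups, covariates = covariate_spec(), seed,
                            contaminants = list(n_cn = 0, n_pctC = 0),
                            suess = suess_model()) {
  stopifnot(!missing(seed), length(groups) >= 1)
  for (g in groups) stopifnot(inherits(g, "group_spec"))
  structure(list(groups = groups, covariates = covariates,
                 seed = as.integer(seed),
                 contaminants = utils::modifyList(list(n_cn = 0, n_pctC = 0),
                                                  contaminants),
                 suess = suess),
            class = "scenario_config")
}

# measured d13C such that lipid + Suess correction reproduces `cor` exactly.
invert_corrections <- function(cor, year, model) {
  shift <- unname(model$atm_series[as.character(year)]) - model$baseline
  (cor + shift + 0.028) / 0.982
}

generate_group_rows <- function(g, cov, model, id_prefix) {
  n <- g$n
  yr_range <- if (is.null(g$year_range)) cov$year_range else g$year_range
  year_mid <- mean(cov$year_range)
  years <- if (yr_range[1] == yr_range[2]) rep(yr_range[1], n) else
    sample(yr_range[1]:yr_range[2], n, replace = TRUE)
  months <- if (is.null(g$months)) {
    sample(1:12, n, replace = TRUE, prob = cov$month_probs)
  } else {
    if (length(g$months) == 1L) rep(g$months, n) else
      sample(g$months, n, replace = TRUE)
  }
  sex <- ifelse(stats::rbinom(n, 1, g$sex_ratio) == 1, "male", "female")

  # all contrasts enter in deviation coding (centred on the group's own
  # realised composition), so the realised group mean stays mu up to the
  # trivariate-normal noise alone
  off <- matrix(0, n, 3, dimnames = list(NULL, ISOTOPES))
  ye <- if (is.null(g$year_effect)) cov$year_effect else g$year_effect
  off <- off + outer(years - mean(years), ye)

  male <- sex == "male"
  off <- off + outer(male - mean(male), cov$sex_effect)

  season <- assign_season(months)
  if (cov$seasonal_d13C_summer != 0) {
    is_summer <- season == "summer_grown"
    off[, "d13C_cor"] <- off[, "d13C_cor"] +
      (is_summer - mean(is_summer)) * cov$seasonal_d13C_summer
  }

  cov_cols <- list()
  for (nm in names(cov$covariates)) {
    cv <- cov$covariates[[nm]]
    val <- cv$mean + cv$year_slope * (years - year_mid) +
      stats::rnorm(n, 0, cv$sd)
    cov_cols[[nm]] <- val
    off <- off + outer(val - mean(val), as_effect(cv$effect))
  }

  draw_iso <- function(m) {
    noise <- MASS::mvrnorm(m, mu = c(0, 0, 0), Sigma = g$sigma)
    if (m == 1) noise <- matrix(noise, nrow = 1)
    noise
  }
  noise <- draw_iso(n)
  # redraw the rare rows whose values would breach the table's sanity
  # bounds (a mild tail truncation; keeps every generated table valid)
  for (it in 1:100) {
    iso <- sweep(noise, 2, g$mu, "+") + off
    meas <- invert_corrections(iso[, 1], years, model)
    bad <- meas < -40 | meas > 0 | iso[, 2] < -10 | iso[, 2] > 20 |
      iso[, 3] < -20 | iso[, 3] > 25
    if (!any(bad)) break
    noise[bad, ] <- draw_iso(sum(bad))
  }
  colnames(iso) <- ISOTOPES

  # keratin-like elemental composition: correlated (pctC, pctN), truncated
  # to the QC acceptance region -- clean rows emulate analysis-grade keratin
  # and always pass; QC failures come only from the explicit contamination
  # mechanisms below
  el <- g$elemental
  draw_elemental <- function(m) {
    z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
    cbind(el$pctC[1] + el$pctC[2] * z1,
          el$pctN[1] + el$pctN[2] * (el$rho * z1 + sqrt(1 - el$rho^2) * z2))
  }
  E <- draw_elemental(n)
  for (it in 1:100) {
    cn <- (E[, 1] * ATOMIC_MASS_N) / (E[, 2] * ATOMIC_MASS_C)
    bad <- E[, 1] <= 0 | E[, 2] <= 0 | E[, 1] > 50 | E[, 2] > 20 |
      cn < 3.0 | cn > 4.05
    if (!any(bad)) break
    E[bad, ] <- draw_elemental(sum(bad))
  }
  pctC <- E[, 1]; pctN <- E[, 2]
  pctS <- pmax(el$pctS[1] + el$pctS[2] * stats::rnorm(n), 0.01)

  contaminated <- stats::rbinom(n, 1, g$qc_fail_rate) == 1
  if (any(contaminated)) {
    kind_c <- stats::rbinom(sum(contaminated), 1, 0.5) == 1
    idx <- which(contaminated)
    # excessive carbon (C/N kept in-window so the exclusion reason is %C)
    pctC[idx[kind_c]] <- stats::runif(sum(kind_c), 51, 60)
    pctN[idx[kind_c]] <- pctC[idx[kind_c]] * ATOMIC_MASS_N /
      (ATOMIC_MASS_C * 3.5)
    # depressed nitrogen driving atomic C/N above the window
    bad_cn <- stats::runif(sum(!kind_c), 4.2, 5.0)
    pctN[idx[!kind_c]] <- pctC[idx[!kind_c]] * ATOMIC_MASS_N /
      (ATOMIC_MASS_C * bad_cn)
  }

  morpho <- list(weight = rep(NA_real_, n), body_length = rep(NA_real_, n),
                 hindfoot_length = rep(NA_real_, n))
  age_class <- rep(NA_character_, n)
  if (identical(g$case_study, 2) || identical(g$case_study, 2L)) {
    for (v in names(morpho)) {
      pm <- cov$morpho$male[[v]]; pf <- cov$morpho$female[[v]]
      morpho[[v]] <- ifelse(male,
                            stats::rnorm(n, pm[1], pm[2]),
                            stats::rnorm(n, pf[1], pf[2]))
    }
    age_class <- sample(c("juvenile", "subadult", "adult"), n,
                        replace = TRUE, prob = c(0.15, 0.2, 0.65))
  }

  df <- data.frame(
    sample_id = sprintf("%s_%03d", id_prefix, seq_len(n)),
    taxon = g$taxon, region = g$region, case_study = g$case_study,
    year = years, month = months, sex = sex,
    d13C_measured = invert_corrections(iso[, "d13C_cor"], years, model),
    d15N = iso[, "d15N"], d34S = iso[, "d34S"],
    pctC = pctC, pctN = pctN, pctS = pctS,
    weight = morpho$weight, body_length = morpho$body_length,
    hindfoot_length = morpho$hindfoot_length, age_class = age_class,
    stringsAsFactors = FALSE
  )
  for (nm in names(cov_cols)) df[[nm]] <- cov_cols[[nm]]
  df
}

#' Generate a synthetic sample table with known ground truth
#'
#' Draws, for each group, `n` individuals whose corrected-space isotope
#' values follow the group's trivariate normal plus the configured year,
#' sex, season and covariate contrasts (all zero-mean, so group means equal
#' `mu`), back-transforms d13C into measured space via the scenario's Suess
#' model (the pipeline's corrections recover the generated values exactly),
#' attaches keratin-like elemental compositions (truncated to the QC
#' acceptance region, so only the contamination mechanisms produce QC
#' failures), morphometrics and covariates, and appends any deterministic
#' contaminant rows. All
#' randomness derives from `config$seed` (base R Mersenne-Twister; the RNG
#' kind is recorded in the truth record): identical config + seed gives an
#' identical table.
#'
#' @param config a [scenario_config()].
#' @return list with `table` (a validated `sample_table`) and `truth` (the
#'   full generative parameter set plus RNG provenance; JSON-serialisable).
#' @export
generate_samples <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  parts <- vector("list", length(config$groups))
  for (i in seq_along(config$groups)) {
    g <- config$groups[[i]]
    prefix <- sprintf("G%02d_%s", i, toupper(substr(g$taxon, 1, 2)))
    parts[[i]] <- generate_group_rows(g, config$covariates, config$suess,
                                      prefix)
  }
  tab <- do.call(rbind, parts)

  n_cont <- config$contaminants$n_cn + config$contaminants$n_pctC
  if (n_cont > 0) {
    src_idx <- rep_len(seq_along(config$groups), n_cont)
    cont <- vector("list", n_cont)
    for (j in seq_len(n_cont)) {
      g <- config$groups[[src_idx[j]]]
      row <- generate_group_rows(
        utils::modifyList(g, list(n = 1L)), config$covariates, config$suess,
        sprintf("CONT%02d", j))
      if (j <= config$contaminants$n_cn) {
        bad_cn <- stats::runif(1, 4.2, 5.0)  # atomic C/N above 4.05
        row$pctN <- row$pctC * ATOMIC_MASS_N / (ATOMIC_MASS_C * bad_cn)
      } else {
        row$pctC <- stats::runif(1, 51, 58)  # %C above the 50 threshold
        row$pctN <- row$pctC * ATOMIC_MASS_N / (ATOMIC_MASS_C * 3.5)
      }
      cont[[j]] <- row
    }
    tab <- rbind(tab, do.call(rbind, cont))
  }

  table <- as_sample_table(tab, provenance = sprintf(
    "synthetic scenario (seed %d, %d groups, %d contaminants)",
    config$seed, length(config$groups), n_cont))
  truth <- list(
    seed = config$seed,
    rng = list(kind = RNGkind()[1], r_version = paste(R.version$major,
                                                      R.version$minor,
                                                      sep = ".")),
    groups = lapply(config$groups, function(g) {
      list(taxon = g$taxon, region = g$region, case_study = g$case_study,
           n = g$n, mu = g$mu, sigma = as.vector(g$sigma),
           qc_fail_rate = g$qc_fail_rate, sex_ratio = g$sex_ratio,
           year_effect = as.list(if (is.null(g$year_effect))
             config$covariates$year_effect else g$year_effect))
    }),
    covariates = list(
      year_range = config$covariates$year_range,
      year_effect = as.list(config$covariates$year_effect),
      sex_effect = as.list(config$covariates$sex_effect),
      seasonal_d13C_summer = config$covariates$seasonal_d13C_summer,
      covariates = lapply(config$covariates$covariates, function(cv) {
        list(mean = cv$mean, sd = cv$sd, year_slope = cv$year_slope,
             effect = as.list(as_effect(cv$effect)))
      })
    ),
    contaminants = config$contaminants
  )
  list(table = table, truth = truth)
}

#' Packaged scenario emulating the study's sample table
#'
#' Seventeen taxon-by-region groups whose sizes, isotope means and SDs are
#' transcribed from the study's summary table (72 retained individuals:
#' 38 wildcats, 23 domestic cats, 11 hybrids across Taunus, Markgraeflerland
#' and five Thuringian regions), with independent isotope axes; sex ratios
#' follow the reported per-region sex counts. Thuringian wildcat groups
#' carry a +0.10 per-mil/year d13C trend (the Harz Foreland group also
#' +0.10 on d34S), a male-female contrast (d13C -1.0, d15N +0.8, d34S +0.3
#' per-mil), a +0.6 per-mil summer-grown d13C contrast, land-use and climate
#' covariates with modest linear effects, and sex-correlated morphometrics.
#' Six contaminant rows (five C/N failures, one %C failure) are appended so
#' the QC stage sees 78 rows and retains 72. Groups with n = 1 reuse their
#' taxon's pooled SDs (the study table prints no SD for singletons).
#'
#' @param seed integer seed stored in the scenario.
#' @param n_scale optional multiplier on every group's n (sizes are rounded,
#'   minimum 1), for large-sample recovery checks.
#' @return a [scenario_config()].
#' @export
paper_like_scenario <- function(seed = 1L, n_scale = 1) {
  # taxon, region, case, n, mean/sd for d13C_cor, d15N, d34S
  rows <- list(
    list("domestic_cat", "Markgraeflerland", 1, 4, c(-19.5, 2.0), c(6.7, 0.9), c(4.8, 1.0), 0.75),
    list("hybrid",       "Markgraeflerland", 1, 5, c(-19.5, 0.9), c(5.0, 2.7), c(3.8, 0.8), 0.60),
    list("wildcat",      "Markgraeflerland", 1, 5, c(-19.9, 0.6), c(3.7, 1.2), c(3.6, 0.9), 0.80),
    list("domestic_cat", "Taunus",           1, 1, c(-19.9, 1.3), c(5.8, 1.5), c(4.9, 1.3), 0.00),
    list("hybrid",       "Taunus",           1, 5, c(-19.1, 1.2), c(3.5, 1.7), c(3.6, 0.6), 0.80),
    list("wildcat",      "Taunus",           1, 10, c(-19.2, 0.9), c(3.0, 1.1), c(3.4, 0.3), 0.50),
    list("domestic_cat", "East Thuringia",   2, 1, c(-20.2, 1.3), c(6.0, 1.5), c(6.5, 1.3), 0.83),
    list("wildcat",      "East Thuringia",   2, 2, c(-20.9, 1.4), c(3.6, 4.1), c(4.6, 1.0), 0.46),
    list("domestic_cat", "Hainich",          2, 7, c(-20.0, 1.6), c(6.1, 2.3), c(6.4, 2.1), 0.83),
    list("hybrid",       "Hainich",          2, 1, c(-24.0, 1.7), c(6.6, 2.3), c(4.2, 0.7), 0.00),
    list("wildcat",      "Hainich",          2, 10, c(-21.0, 1.2), c(3.6, 1.8), c(5.2, 0.7), 0.46),
    list("domestic_cat", "Harz Foreland",    2, 1, c(-18.9, 1.3), c(5.6, 1.5), c(5.8, 1.3), 0.83),
    list("wildcat",      "Harz Foreland",    2, 6, c(-20.9, 1.1), c(3.2, 2.0), c(4.7, 1.0), 0.46),
    list("domestic_cat", "Thuringian Basin", 2, 2, c(-20.2, 0.1), c(5.4, 2.1), c(6.1, 0.7), 0.83),
    list("wildcat",      "Thuringian Basin", 2, 1, c(-22.2, 1.4), c(6.7, 1.7), c(5.8, 1.1), 0.46),
    list("domestic_cat", "Thuringian Forest", 2, 7, c(-19.9, 1.3), c(5.7, 1.0), c(6.1, 0.3), 0.83),
    list("wildcat",      "Thuringian Forest", 2, 4, c(-21.9, 0.9), c(4.6, 1.9), c(4.8, 1.0), 0.46)
  )
  wc_trend <- c(d13C_cor = 0.10)
  sex_effect <- c(d13C_cor = -1.0, d15N = 0.8, d34S = 0.3)
  seasonal_amp <- 0.6
  covs <- list(
    pasture = list(mean = 45, sd = 8, effect = c(d13C_cor = 0.04)),
    rapeseed = list(mean = 12, sd = 3, year_slope = 0.15,
                    effect = c(d13C_cor = 0.06)),
    cereals = list(mean = 60, sd = 10, effect = c(d13C_cor = 0.02)),
    maize = list(mean = 8, sd = 2, effect = c(d13C_cor = 0.05)),
    summer_temp = list(mean = 16.5, sd = 0.8, year_slope = 0.04,
                       effect = c(d34S = 0.10)),
    winter_precip = list(mean = 180, sd = 30)
  )
  var_year <- (27^2 - 1) / 12   # discrete uniform 1995..2021

  # The printed group SDs are *observed* dispersions, which in the source
  # data already contain the year/sex/season/covariate structure; the
  # trivariate noise therefore gets the residual variance (floored at 30%
  # of the printed SD) so that the generated groups reproduce the printed
  # SDs rather than inflating them.
  residual_sd <- function(table_sd, r, is_case1, ye) {
    p <- r[[8]]
    extra <- stats::setNames(numeric(3), ISOTOPES)
    extra <- extra + p * (1 - p) * as_effect(sex_effect)^2
    p_s <- if (is_case1) 2 / 3 else 5 / 12   # share of summer-grown months
    extra["d13C_cor"] <- extra["d13C_cor"] + p_s * (1 - p_s) * seasonal_amp^2
    vy <- if (is_case1) 0 else var_year
    extra <- extra + as_effect(ye)^2 * vy
    for (cv in covs) {
      ys <- if (is.null(cv$year_slope)) 0 else cv$year_slope
      extra <- extra + as_effect(cv$effect)^2 * (cv$sd^2 + ys^2 * vy)
    }
    sqrt(pmax(table_sd^2 - extra, (0.3 * table_sd)^2))
  }

  groups <- lapply(rows, function(r) {
    is_case1 <- r[[3]] == 1
    is_thur_wc <- r[[1]] == "wildcat" && r[[3]] == 2
    ye <- if (is_thur_wc) {
      if (r[[2]] == "Harz Foreland") c(wc_trend, d34S = 0.10) else wc_trend
    } else NULL
    table_sd <- c(r[[5]][2], r[[6]][2], r[[7]][2])
    group_spec(
      taxon = r[[1]], region = r[[2]], case_study = r[[3]],
      n = max(1L, as.integer(round(r[[4]] * n_scale))),
      mu = c(r[[5]][1], r[[6]][1], r[[7]][1]),
      sigma = residual_sd(table_sd, r, is_case1, ye),
      sex_ratio = r[[8]],
      year_range = if (is_case1) c(2021, 2021) else NULL,
      months = if (is_case1) 3:5 else NULL,
      year_effect = ye
    )
  })
  cov <- covariate_spec(
    year_range = c(1995, 2021),
    sex_effect = sex_effect,
    seasonal_d13C_summer = seasonal_amp,
    covariates = covs
  )
  scenario_config(groups = groups, covariates = cov, seed = seed,
                  contaminants = list(n_cn = 5, n_pctC = 1))
}
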