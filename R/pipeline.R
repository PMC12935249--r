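# Config-driven end-to-end pipeline: read/simulate -> QC -> corrections ->
# group summaries -> Layman/SEA/SEAb -> overlaps -> seasonal trends ->
# rank-sum / t-test / correlation screens -> CSV + JSON + log outputs.

PIPELINE_STAGES <- c("input", "qc", "corrections", "summaries", "niche",
                     "seab", "overlap", "trends", "tests", "screen", "write")

# Child seeds: a fixed affine map per stage index, so adding a stage never
# perturbs the randomness of earlier stages.
child_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) + 97561 * stage_index) %% 2147483629)
}

#' Pipeline configuration
#'
#' Exactly one of `input` (path to a CSV/TSV sample table) or `scenario`
#' (a [scenario_config()], or the string `"paper_like"`) must be given.
#'
#' @param input path to a sample table, or `NULL`.
#' @param scenario a [scenario_config()], `"paper_like"`, or `NULL`.
#' @param qc a [qc_config()].
#' @param suess a [suess_model()] or path to a series CSV.
#' @param mcmc an [mcmc_config()] for the SEAb stage.
#' @param run_seab compute SEAb posteriors? (the slowest stage).
#' @param overlap_coverage coverage passed to [ellipse_overlap()].
#' @param screen_variables variables for [correlation_screen()]; `NULL`
#'   auto-detects covariate columns plus morphometrics, sex and year.
#' @param min_group_n groups smaller than this get descriptive summaries
#'   only; niche metrics are marked not computable.
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; all stochastic stages derive from it.
#' @param log_level `"info"` or `"quiet"`.
#' @param dialect input file dialect.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, scenario = NULL, qc = qc_config(),
                            suess = NULL, mcmc = mcmc_config(),
                            run_seab = TRUE,
                            overlap_coverage = STANDARD_ELLIPSE_COVERAGE,
                            screen_variables = NULL, min_group_n = 3L,
                            out_dir = tempfile("felisotope_run_"),
                            seed = 1L, log_level = c("info", "quiet"),
                            dialect = "csv") {
  if (is.null(input) == is.null(scenario)) {
    stop("exactly one of `input` and `scenario` must be supplied",
         call. = FALSE)
  }
  if (identical(scenario, "paper_like")) {
    scenario <- paper_like_scenario(seed = child_seed(seed, 1L))
  }
  if (is.character(suess)) suess <- suess_model(suess)
  if (is.null(suess)) suess <- suess_model()
  structure(list(input = input, scenario = scenario, qc = qc, suess = suess,
                 mcmc = mcmc, run_seab = run_seab,
                 overlap_coverage = overlap_coverage,
                 screen_variables = screen_variables,
                 min_group_n = as.integer(min_group_n),
                 out_dir = out_dir, seed = as.integer(seed),
                 log_level = match.arg(log_level), dialect = dialect),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  strip <- config
  strip$out_dir <- NULL                  # hash the analysis, not the paths
  writeLines(yaml::as.yaml(lapply(strip, function(x) {
    if (is.function(x)) "<function>" else x
  })), tmp)
  unname(tools::md5sum(tmp))
}

# group assignment used for summaries/niche: per-region groups plus pooled
# "All samples" per taxon, plus pooled "Thuringia" (case study 2) groups.
pipeline_groups <- function(table) {
  df <- as.data.frame(table)
  out <- list()
  add <- function(taxon, region_label, idx) {
    if (!length(idx)) return()
    out[[length(out) + 1]] <<- list(taxon = taxon, region = region_label,
                                    idx = idx)
  }
  for (tx in unique(df$taxon)) {
    add(tx, "All samples", which(df$taxon == tx))
    thur <- which(df$taxon == tx & !is.na(df$case_study) & df$case_study == 2)
    regions <- unique(df$region[df$taxon == tx])
    for (rg in regions[!is.na(regions)]) {
      add(tx, rg, which(df$taxon == tx & df$region == rg))
    }
    if (length(thur) && length(unique(df$region[thur])) > 1) {
      add(tx, "Thuringia", thur)
    }
  }
  out
}

log_line <- function(lines_env, config, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  lines_env$lines <- c(lines_env$lines, line)
  if (config$log_level == "info") message(line)
  invisible(NULL)
}

run_stage <- function(name, lines_env, config, expr) {
  log_line(lines_env, config, paste("stage", name, "start"))
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: input (read or simulate) -> elemental QC ->
#' lipid + Suess corrections -> per-group descriptive summaries -> Layman
#' metrics and SEA/SEAc (groups below `min_group_n` are summarised
#' descriptively and marked `not_computable`) -> SEAb posteriors (optional)
#' -> hybrid/domestic-vs-wildcat ellipse overlaps -> per-region seasonal
#' trend fits (OLS and Huber side by side) -> pairwise Wilcoxon (BH
#' corrected) and sex t-tests -> Pearson correlation screen on Thuringian
#' (case-study-2) wildcats. All result tables are written as CSV into
#' `out_dir` together with a JSON run report (config echo, config hash,
#' seed, stage seeds, counts, versions) and a plain-text log; every CSV
#' carries the config hash as a comment-free sidecar entry in the report. A
#' second run with identical config and seed reproduces every numeric
#' output exactly, stochastic stages included.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `status` (0 on success), `outputs` (paths),
#'   and `results` (all in-memory result tables).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  lines_env <- new.env(); lines_env$lines <- character()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_line(lines_env, config, paste("run start, config hash", hash))

  ## input
  inp <- run_stage("input", lines_env, config, {
    if (!is.null(config$input)) {
      list(table = read_sample_table(config$input, config$dialect),
           truth = NULL)
    } else {
      generate_samples(config$scenario)
    }
  })
  table0 <- inp$table
  log_line(lines_env, config, sprintf("input: %d samples", nrow(table0)))

  ## qc
  qc <- run_stage("qc", lines_env, config, apply_qc(table0, config$qc))
  table <- qc$table
  log_line(lines_env, config,
           sprintf("qc: retained %d of %d", qc$report$totals$n_retained,
                   qc$report$totals$n_input))

  ## corrections
  table <- run_stage("corrections", lines_env, config,
                     correct_d13c(table, config$suess))

  groups <- pipeline_groups(table)
  df <- as.data.frame(table)
  group_label <- function(g) sprintf("%s | %s", g$taxon, g$region)

  ## summaries (Table-1 analogue)
  summaries <- run_stage("summaries", lines_env, config, {
    do.call(rbind, lapply(groups, function(g) {
      sub <- df[g$idx, ]
      one <- function(col) {
        v <- sub[[col]][is.finite(sub[[col]])]
        if (!length(v)) return(c(NA, NA, NA, NA))
        c(mean(v), stats::sd(v), min(v), max(v))
      }
      s13 <- one("d13C_cor"); s15 <- one("d15N"); s34 <- one("d34S")
      data.frame(taxon = g$taxon, region = g$region, n = length(g$idx),
                 d13C_mean = s13[1], d13C_sd = s13[2], d13C_min = s13[3],
                 d13C_max = s13[4],
                 d15N_mean = s15[1], d15N_sd = s15[2], d15N_min = s15[3],
                 d15N_max = s15[4],
                 d34S_mean = s34[1], d34S_sd = s34[2], d34S_min = s34[3],
                 d34S_max = s34[4], stringsAsFactors = FALSE)
    }))
  })

  ## niche metrics (Table-2 analogue)
  niche <- run_stage("niche", lines_env, config, {
    do.call(rbind, lapply(groups, function(g) {
      sub <- df[g$idx, ]
      n <- nrow(sub)
      base <- data.frame(taxon = g$taxon, region = g$region, n = n,
                         status = "ok",
                         dC_range = NA_real_, dN_range = NA_real_,
                         TA = NA_real_, CD = NA_real_, NND = NA_real_,
                         SDNND = NA_real_, SEA = NA_real_, SEAc = NA_real_,
                         stringsAsFactors = FALSE)
      if (n < config$min_group_n) {
        base$status <- "not_computable"
        return(base)
      }
      lay <- layman_metrics(sub$d13C_cor, sub$d15N)
      base$dC_range <- lay$dC_range; base$dN_range <- lay$dN_range
      base$TA <- lay$TA; base$CD <- lay$CD; base$NND <- lay$NND
      base$SDNND <- lay$SDNND
      fit <- tryCatch(fit_standard_ellipse(sub$d13C_cor, sub$d15N),
                      error = function(e) NULL)
      if (is.null(fit)) {
        base$status <- "degenerate_ellipse"
      } else {
        base$SEA <- fit$SEA; base$SEAc <- fit$SEAc
      }
      base
    }))
  })

  ## SEAb
  seab <- NULL
  if (config$run_seab) {
    seab_seed <- child_seed(config$seed, 6L)
    seab <- run_stage("seab", lines_env, config, {
      rows <- list()
      for (i in seq_along(groups)) {
        g <- groups[[i]]
        sub <- df[g$idx, ]
        if (nrow(sub) < config$min_group_n) next
        post <- tryCatch(
          sample_seab(sub$d13C_cor, sub$d15N, config$mcmc,
                      seed = child_seed(seab_seed, i)),
          error = function(e) NULL)
        if (is.null(post)) next
        s <- post$summaries
        rows[[length(rows) + 1]] <- data.frame(
          taxon = g$taxon, region = g$region, n = post$n,
          n_draws = post$n_draws, seab_mean = s$mean, seab_mode = s$mode,
          ci95_lo = s$ci95[1], ci95_hi = s$ci95[2],
          ci75_lo = s$ci75[1], ci75_hi = s$ci75[2],
          ci50_lo = s$ci50[1], ci50_hi = s$ci50[2],
          stringsAsFactors = FALSE)
      }
      if (length(rows)) do.call(rbind, rows) else NULL
    })
  }

  ## overlap: how much of the wildcat ellipse do hybrids / domestic cats occupy
  overlap <- run_stage("overlap", lines_env, config, {
    fits <- lapply(groups, function(g) {
      sub <- df[g$idx, ]
      if (nrow(sub) < config$min_group_n) return(NULL)
      tryCatch(fit_standard_ellipse(sub$d13C_cor, sub$d15N),
               error = function(e) NULL)
    })
    names(fits) <- vapply(groups, group_label, character(1))
    regions <- unique(vapply(groups, function(g) g$region, character(1)))
    rows <- list()
    for (rg in regions) {
      wc <- fits[[sprintf("wildcat | %s", rg)]]
      if (is.null(wc)) next
      for (other in c("hybrid", "domestic_cat")) {
        fo <- fits[[sprintf("%s | %s", other, rg)]]
        if (is.null(fo)) next
        ov <- ellipse_overlap(fo, wc, coverage = config$overlap_coverage)
        rows[[length(rows) + 1]] <- data.frame(
          region = rg, taxon_a = other, taxon_b = "wildcat",
          area_a = ov$area_A, area_b = ov$area_B,
          area_intersection = ov$area_intersection,
          pct_of_wildcat = ov$prop_of_B, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  ## trends: per region x taxon x isotope, all samples + per season
  trends <- run_stage("trends", lines_env, config, {
    df$season <- assign_season(df$month)
    rows <- list()
    combos <- unique(df[!is.na(df$region), c("taxon", "region")])
    for (k in seq_len(nrow(combos))) {
      sub_all <- df[df$taxon == combos$taxon[k] &
                      !is.na(df$region) & df$region == combos$region[k], ]
      for (season in c("all", "summer_grown", "winter_grown")) {
        sub <- if (season == "all") sub_all else
          sub_all[sub_all$season == season, ]
        for (iso in c("d13C_cor", "d15N", "d34S")) {
          v <- sub[[iso]]; y <- sub$year
          ok <- is.finite(v) & is.finite(y)
          if (sum(ok) < 3 || length(unique(y[ok])) < 2) next
          for (method in c("ols", "huber")) {
            fit <- tryCatch(fit_trend(y[ok], v[ok], method),
                            error = function(e) NULL)
            if (is.null(fit)) next
            rows[[length(rows) + 1]] <- data.frame(
              taxon = combos$taxon[k], region = combos$region[k],
              season = season, isotope = iso, method = method,
              slope = fit$slope, intercept = fit$intercept,
              r_squared = fit$r_squared, p_value = fit$p_value,
              n = fit$n, converged = fit$converged,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  ## pairwise rank-sum tests + sex t-tests
  tests <- run_stage("tests", lines_env, config, {
    wil <- list()
    for (iso in c("d13C_cor", "d15N", "d34S")) {
      v <- df[[iso]]
      ok <- is.finite(v)
      if (length(unique(df$taxon[ok])) < 2) next
      w <- pairwise_wilcoxon(v[ok], df$taxon[ok])
      w$isotope <- iso
      wil[[length(wil) + 1]] <- w
    }
    wil <- if (length(wil)) do.call(rbind, wil) else NULL

    thur_wc <- df[df$taxon == "wildcat" & !is.na(df$case_study) &
                    df$case_study == 2 & df$sex != "unknown", ]
    tt <- list()
    for (iso in c("d13C_cor", "d15N", "d34S")) {
      f <- thur_wc[[iso]][thur_wc$sex == "female"]
      m <- thur_wc[[iso]][thur_wc$sex == "male"]
      res <- tryCatch(pooled_t_test(f, m), error = function(e) NULL)
      if (is.null(res)) next
      tt[[length(tt) + 1]] <- data.frame(
        isotope = iso, group_a = "female", group_b = "male",
        t = res$t, df = res$df, p = res$p, mean_a = res$mean_a,
        mean_b = res$mean_b, n_a = res$n_a, n_b = res$n_b,
        stringsAsFactors = FALSE)
    }
    list(wilcoxon = wil, t_tests = if (length(tt)) do.call(rbind, tt) else NULL)
  })

  ## correlation screen on Thuringian wildcats
  screen <- run_stage("screen", lines_env, config, {
    sub <- df[df$taxon == "wildcat" & !is.na(df$case_study) &
                df$case_study == 2, ]
    if (nrow(sub) < 3) return(NULL)
    vars <- config$screen_variables
    if (is.null(vars)) {
      vars <- c(attr(table, "covariate_cols"),
                "weight", "body_length", "hindfoot_length", "sex", "year")
      vars <- vars[vars %in% c(names(df), "sex")]
    }
    sub_t <- structure(sub, class = c("sample_table", "data.frame"),
                       covariate_cols = attr(table, "covariate_cols"))
    correlation_screen(sub_t, variables = vars)
  })

  ## write outputs
  outputs <- run_stage("write", lines_env, config, {
    paths <- list()
    emit <- function(obj, name) {
      if (is.null(obj)) return()
      p <- file.path(config$out_dir, paste0(name, ".csv"))
      write_report(table, obj, p, config = list(config_hash = hash),
                   seed = config$seed)
      paths[[name]] <<- p
    }
    emit(summaries, "group_summaries")
    emit(qc$report$per_sample, "qc_report")
    emit(niche, "niche_metrics")
    # paper-comparison view: 1 decimal for per-mil(^2) metrics
    niche_round <- niche
    for (col in c("dC_range", "dN_range", "TA", "CD", "NND", "SDNND",
                  "SEA", "SEAc")) {
      niche_round[[col]] <- round(niche_round[[col]], 1)
    }
    emit(niche_round, "niche_metrics_rounded")
    emit(seab, "seab_posteriors")
    emit(overlap, "overlap")
    emit(trends, "trends")
    emit(tests$wilcoxon, "wilcoxon_tests")
    emit(tests$t_tests, "t_tests")
    emit(screen, "correlation_screen")

    report <- list(
      config_hash = hash,
      seed = config$seed,
      stage_seeds = stats::setNames(
        lapply(seq_along(PIPELINE_STAGES), function(i) child_seed(config$seed, i)),
        PIPELINE_STAGES),
      software = list(package = "felisotope",
                      version = as.character(utils::packageVersion("felisotope")),
                      r_version = paste(R.version$major, R.version$minor,
                                        sep = ".")),
      counts = list(n_input = qc$report$totals$n_input,
                    n_retained = qc$report$totals$n_retained,
                    n_excluded_by_reason =
                      as.list(qc$report$totals$n_excluded_by_reason),
                    n_groups = length(groups)),
      outputs = lapply(paths, basename),
      truth = inp$truth,
      started = format(t0, "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    paths$run_report <- file.path(config$out_dir, "run_report.json")
    paths
  })

  log_line(lines_env, config, "run complete")
  writeLines(lines_env$lines, file.path(config$out_dir, "pipeline.log"))
  outputs$log <- file.path(config$out_dir, "pipeline.log")

  invisible(list(status = 0L, outputs = outputs,
                 results = list(table = table, qc = qc$report,
                                summaries = summaries, niche = niche,
                                seab = seab, overlap = overlap,
                                trends = trends, wilcoxon = tests$wilcoxon,
                                t_tests = tests$t_tests, screen = screen,
                                truth = inp$truth, config_hash = hash)))
}
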