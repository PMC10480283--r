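#' Cohort characteristics summary
#'
#' Counts and percentages of the simulated (or observed) cohort truth in the
#' style of a baseline-characteristics table: cT-stage groups, cN-stage,
#' the TRG distribution, the response categorisation ((near-)complete,
#' TRG 1-2 or sustained clinical complete response, versus incomplete), and
#' the CRT-to-surgery interval mean and SD. Percentages are rounded half-up
#' to whole percents.
#'
#' @param truth Cohort truth table (see [simulate_truth()]); needs columns
#'   `t_stage`, `n_stage`, `trg`, `ww_sustained`, `ncr`, `interval_weeks`.
#' @return Tibble with `block`, `level`, `n`, `percent`, `value` (the
#'   numeric blocks use `value` and leave `n`/`percent` `NA`).
#' @export
summarize_cohort <- function(truth) {
  if (nrow(truth) == 0) abort("empty cohort")
  n <- nrow(truth)
  # round half-up to whole percents, matching clinical-table style
  pct <- function(k) floor(100 * k / n + 0.5)
  t_group <- dplyr::case_when(
    truth$t_stage %in% c("t1", "t2") ~ "cT1-2",
    truth$t_stage %in% c("t3a", "t3b", "t3c", "t3d") ~ "cT3",
    .default = "cT4"
  )
  block_counts <- function(block, x, levels) {
    k <- unname(vapply(levels, function(l) sum(x == l, na.rm = TRUE),
                       numeric(1)))
    tibble::tibble(block = block, level = levels, n = as.integer(k),
                   percent = pct(k), value = NA_real_)
  }
  trg_eff <- ifelse(truth$ww_sustained, 1L, truth$trg)
  out <- dplyr::bind_rows(
    tibble::tibble(block = "patients", level = "n", n = n,
                   percent = 100, value = NA_real_),
    block_counts("cT-stage", t_group, c("cT1-2", "cT3", "cT4")),
    block_counts("cN-stage", truth$n_stage, c("n0", "n1", "n2")),
    block_counts("TRG", as.character(trg_eff), as.character(1:5)),
    block_counts("response", ifelse(truth$ncr, "(near-)complete (TRG1-2)",
                                    "incomplete (TRG3-5)"),
                 c("(near-)complete (TRG1-2)", "incomplete (TRG3-5)")),
    tibble::tibble(block = "interval_weeks",
                   level = c("mean", "sd"),
                   n = NA_integer_, percent = NA_real_,
                   value = c(mean(truth$interval_weeks),
                             sd(truth$interval_weeks)))
  )
  out
}

# Stable hash of the resolved configuration, so outputs from different runs
# are detectable when mixed. Polynomial rolling hash over the serialised
# config text, kept below 2^31 so double arithmetic stays exact.
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 15)),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

write_report_csv <- function(df, path, hash) {
  cat("# config_hash: ", hash, "\n", file = path, sep = "")
  readr::write_csv(df, path, na = "", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full simulate-score-evaluate-report pipeline
#'
#' Simulates a multireader study cohort, scores every reader's assessments
#' with the three methods, and writes the complete report bundle: cohort
#' truth, assessments, long scores, outcome table, cohort summary,
#' diagnostic-performance report, interobserver-agreement report,
#' reader-experience effect table, interval-model fits, and a JSON manifest
#' recording the resolved configuration, seeds, and a config hash. Re-running
#' with the same configuration and seed reproduces every file bitwise.
#'
#' @param config A [sim_config()].
#' @param output_dir Directory for the bundle (created if needed).
#' @param seed Master seed (defaults to `config$seed`; overrides it in the
#'   resolved config).
#' @param n_boot Bootstrap resamples for the AUC and alpha CIs.
#' @param ci Attach bootstrap CIs to the agreement report (slower).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with every report table and the file paths.
#' @export
run_pipeline <- function(config = sim_config(), output_dir, seed = config$seed,
                         n_boot = 2000, ci = FALSE, quiet = FALSE) {
  config <- validate_sim_config(unclass(config))
  config$seed <- as.integer(seed)
  if (is.null(config$intercept)) config$intercept <- calibrate_intercept(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    say("stage %-12s done in %.2fs", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }
  seeds <- stage_seeds(config$seed, 10)
  hash <- config_hash(config)

  study <- stage("simulate", simulate_study(config, seed = config$seed))
  truth <- study$truth
  outcomes <- truth[c("patient_id", "trg", "ww_sustained", "ncr",
                      "interval_weeks")]
  cohort <- stage("summarise", summarize_cohort(truth))
  perf <- stage("performance",
                performance_table(study$scores, outcomes, study$panel,
                                  n_boot = n_boot, seed = seeds[6]))
  agree <- stage("agreement",
                 agreement_table(study$scores, study$panel,
                                 assessments = study$assessments,
                                 ci = ci, n_boot = max(n_boot, 1000),
                                 seed = seeds[7]))
  records <- correctness_records(study$scores, outcomes, study$panel)
  effects <- stage("effects", experience_effect_table(records))
  interval_fits <- stage("interval", purrr::map_dfr(
    intersect(SCORE_METHODS, unique(records$method)), function(m) {
      fit <- fit_interval_model(
        interval_correctness(records[records$method == m, ], outcomes))
      dplyr::bind_cols(tibble::tibble(method = m),
                       tidy(fit)[2, c("estimate", "std.error", "conf.low",
                                      "conf.high", "p.value")])
    }))

  paths <- list(
    truth = file.path(output_dir, "cohort_truth.csv"),
    assessments = file.path(output_dir, "assessments.csv"),
    scores = file.path(output_dir, "scores.csv"),
    outcomes = file.path(output_dir, "outcomes.csv"),
    cohort_summary = file.path(output_dir, "cohort_summary.csv"),
    performance = file.path(output_dir, "performance.csv"),
    agreement = file.path(output_dir, "agreement.csv"),
    effects = file.path(output_dir, "experience_effects.csv"),
    interval = file.path(output_dir, "interval_model.csv"),
    manifest = file.path(output_dir, "manifest.json")
  )
  tables <- list(truth = truth, assessments = study$assessments,
                 scores = study$scores, outcomes = outcomes,
                 cohort_summary = cohort, performance = perf,
                 agreement = agree, effects = effects,
                 interval = interval_fits)
  for (nm in names(tables)) {
    write_report_csv(tables[[nm]], paths[[nm]], hash)
  }
  manifest <- list(
    config = config[setdiff(names(config), "feature_error")],
    feature_error = config$feature_error,
    config_hash = hash,
    seed = config$seed,
    stage_seeds = seeds,
    n_boot = n_boot,
    files = lapply(paths, basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(tables, list(panel = study$panel, config = config,
                           paths = paths)))
}
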