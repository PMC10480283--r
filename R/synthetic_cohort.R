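#' Configuration for the synthetic multireader cohort generator
#'
#' Builds and validates the full parameter set of the synthetic study
#' generator. Defaults emulate a 90-patient rectal cancer cohort read by 5
#' expert and 17 non-expert radiologists, with a (near-)complete response
#' (nCR) prevalence of 0.49, baseline cT-stage margins of roughly 3% cT1-2 /
#' 76% cT3 / 20% cT4, cN margins of 13/21/66%, a TRG distribution of
#' 30/19/32/17/2%, and a chemoradiotherapy-to-surgery interval of 11 ± 2.5
#' weeks (truncated at 6).
#'
#' The generative model: per-patient staging features are drawn from the
#' configured marginals, with tumor size log-normal and the binary features
#' (heterogeneous signal, irregular shape, EMVI, MRF) Bernoulli with
#' T-stage-dependent log-odds so that advanced tumors carry more high-risk
#' features; the nCR outcome follows a logistic link on the seven high-risk
#' indicators; TRG is drawn conditionally on nCR status; readers perceive
#' each feature through an experience-stratum error channel in which misses
#' are more common than false calls (readers in doubt call "no").
#'
#' @param n_patients Number of patients (default 90).
#' @param n_expert_readers,n_nonexpert_readers Reader panel sizes
#'   (defaults 5 and 17).
#' @param prevalence_ncr Target marginal probability of (near-)complete
#'   response (default 0.49).
#' @param t_group_probs Probabilities of the cT1-2 / cT3 / cT4 stage groups
#'   (named vector; defaults are the cohort counts 3/68/18 normalised).
#' @param t12_split,t3_split Conditional splits of cT1-2 into T1/T2 and of
#'   cT3 into T3a-d.
#' @param n_stage_probs Probabilities of cN0/cN1/cN2 (defaults 12/19/59 of 90).
#' @param size_median_cm,size_sdlog Median (cm) and log-scale SD of the
#'   log-normal tumor-size distribution.
#' @param feature_base_logodds,feature_t_slope Base log-odds and per-unit
#'   T-stage slope for the four T-stage-linked binary features
#'   (`signal`, `shape`, `emvi`, `mrf`); the T-stage covariate is the stage
#'   rank centred at T3b and scaled to \[-1, 1\].
#' @param risk_coefficients Log-odds contribution of each of the 7 high-risk
#'   indicators to the nCR outcome (named, negative = high risk lowers the
#'   response probability).
#' @param intercept Outcome-model intercept; `NULL` (default) auto-calibrates
#'   it so the marginal nCR probability matches `prevalence_ncr`.
#' @param trg_given_ncr,trg_given_noncr Conditional TRG distributions
#'   (over grades 1-2 and 3-5 respectively).
#' @param ww_fraction_of_cr Fraction of complete responders (TRG 1) followed
#'   in a watch-and-wait program, for whom a sustained clinical complete
#'   response replaces histopathology (default 6/27).
#' @param interval_mean_weeks,interval_sd_weeks,interval_min_weeks Mean, SD,
#'   and lower truncation (weeks) of the CRT-to-surgery interval.
#' @param feature_error Per-stratum perception error rates: a list with
#'   elements `expert` and `nonexpert`, each a list with `p_miss` (present
#'   feature reported absent), `p_false_call` (absent feature reported
#'   present), `t_adjacent` (probability the T-stage is perceived as an
#'   adjacent category), and `size_sdlog` (multiplicative log-scale size
#'   noise). Expert error rates should not exceed non-expert rates.
#' @param seed Master seed; per-stage sub-streams are derived from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 90,
                       n_expert_readers = 5,
                       n_nonexpert_readers = 17,
                       prevalence_ncr = 0.49,
                       t_group_probs = c(t12 = 3, t3 = 68, t4 = 18) / 89,
                       t12_split = c(t1 = 0.3, t2 = 0.7),
                       t3_split = c(t3a = 0.3, t3b = 0.3, t3c = 0.3, t3d = 0.1),
                       n_stage_probs = c(n0 = 12, n1 = 19, n2 = 59) / 90,
                       size_median_cm = 4.5,
                       size_sdlog = 0.4,
                       feature_base_logodds = c(signal = 0, shape = 0,
                                                emvi = -1, mrf = -1.5),
                       feature_t_slope = c(signal = 1.5, shape = 1.5,
                                           emvi = 1.5, mrf = 2),
                       risk_coefficients = c(t_stage = -0.5, size = -0.5,
                                             signal = -0.5, shape = -0.5,
                                             n_stage = -0.5, emvi = -0.5,
                                             mrf = -0.5),
                       intercept = NULL,
                       trg_given_ncr = c(`1` = 30, `2` = 19) / 49,
                       trg_given_noncr = c(`3` = 32, `4` = 17, `5` = 2) / 51,
                       ww_fraction_of_cr = 6 / 27,
                       interval_mean_weeks = 11,
                       interval_sd_weeks = 2.5,
                       interval_min_weeks = 6,
                       feature_error = list(
                         expert = list(p_miss = 0.15, p_false_call = 0.05,
                                       t_adjacent = 0.15, size_sdlog = 0.08),
                         nonexpert = list(p_miss = 0.30, p_false_call = 0.10,
                                          t_adjacent = 0.30, size_sdlog = 0.15)
                       ),
                       seed = 20230626) {
  cfg <- list(
    n_patients = n_patients, n_expert_readers = n_expert_readers,
    n_nonexpert_readers = n_nonexpert_readers, prevalence_ncr = prevalence_ncr,
    t_group_probs = t_group_probs, t12_split = t12_split, t3_split = t3_split,
    n_stage_probs = n_stage_probs, size_median_cm = size_median_cm,
    size_sdlog = size_sdlog, feature_base_logodds = feature_base_logodds,
    feature_t_slope = feature_t_slope, risk_coefficients = risk_coefficients,
    intercept = intercept, trg_given_ncr = trg_given_ncr,
    trg_given_noncr = trg_given_noncr, ww_fraction_of_cr = ww_fraction_of_cr,
    interval_mean_weeks = interval_mean_weeks,
    interval_sd_weeks = interval_sd_weeks,
    interval_min_weeks = interval_min_weeks,
    feature_error = feature_error, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1)
  if (cfg$n_expert_readers < 0 || cfg$n_nonexpert_readers < 0 ||
      cfg$n_expert_readers + cfg$n_nonexpert_readers < 1) {
    abort("the reader panel needs at least one reader")
  }
  check_probs <- function(p, what) {
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9) {
      abort(paste0(what, " must be probabilities summing to 1"))
    }
  }
  check_probs(cfg$t_group_probs, "t_group_probs")
  check_probs(cfg$t12_split, "t12_split")
  check_probs(cfg$t3_split, "t3_split")
  check_probs(cfg$n_stage_probs, "n_stage_probs")
  check_probs(cfg$trg_given_ncr, "trg_given_ncr")
  check_probs(cfg$trg_given_noncr, "trg_given_noncr")
  if (cfg$prevalence_ncr <= 0 || cfg$prevalence_ncr >= 1) {
    abort("prevalence_ncr must be in (0, 1)")
  }
  if (cfg$ww_fraction_of_cr < 0 || cfg$ww_fraction_of_cr > 1) {
    abort("ww_fraction_of_cr must be in [0, 1]")
  }
  for (s in c("expert", "nonexpert")) {
    fe <- cfg$feature_error[[s]]
    rates <- unlist(fe[c("p_miss", "p_false_call", "t_adjacent")])
    if (any(rates < 0) || any(rates > 1) || fe$size_sdlog < 0) {
      abort("feature_error rates must be valid probabilities / non-negative SDs")
    }
  }
  stopifnot(length(cfg$risk_coefficients) == 7)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d patients, %d expert + %d non-expert readers\n",
              x$n_patients, x$n_expert_readers, x$n_nonexpert_readers))
  cat(sprintf("  target nCR prevalence %.2f; seed %d\n",
              x$prevalence_ncr, x$seed))
  invisible(x)
}

# T-stage covariate for the feature model: stage rank centred at T3b,
# scaled to [-1, 1].
t_stage_covariate <- function(t_stage) {
  (match(t_stage, T_STAGE_LEVELS) - 4) / 3
}

# Draw n true staging-feature profiles under the configured marginals.
draw_profiles <- function(config, n) {
  grp <- sample(c("t12", "t3", "t4"), n, replace = TRUE,
                prob = config$t_group_probs)
  t_stage <- character(n)
  t_stage[grp == "t12"] <- sample(names(config$t12_split),
                                  sum(grp == "t12"), replace = TRUE,
                                  prob = config$t12_split)
  t_stage[grp == "t3"] <- sample(names(config$t3_split),
                                 sum(grp == "t3"), replace = TRUE,
                                 prob = config$t3_split)
  t_stage[grp == "t4"] <- "t4"
  z <- t_stage_covariate(t_stage)
  bern <- function(feature) {
    p <- plogis(config$feature_base_logodds[[feature]] +
                  config$feature_t_slope[[feature]] * z)
    runif(n) < p
  }
  tibble::tibble(
    t_stage = t_stage,
    size_cm = rlnorm(n, meanlog = log(config$size_median_cm),
                     sdlog = config$size_sdlog),
    signal  = ifelse(bern("signal"), "heterogeneous", "homogeneous"),
    shape   = ifelse(bern("shape"), "irregular", "regular"),
    n_stage = sample(names(config$n_stage_probs), n, replace = TRUE,
                     prob = config$n_stage_probs),
    emvi    = bern("emvi"),
    mrf     = bern("mrf")
  )
}

# 0/1 matrix of the 7 high-risk indicators, in risk_coefficients order.
high_risk_indicators <- function(profiles) {
  cls <- classify_features(profiles)
  cols <- paste0("risk_", c("t_stage", "size", "signal", "shape",
                            "n_stage", "emvi", "mrf"))
  (as.matrix(cls[cols]) == "high") * 1
}

#' Calibrate the outcome-model intercept to a target nCR prevalence
#'
#' Finds the logistic intercept at which the marginal probability of a
#' (near-)complete response under the configured feature distribution equals
#' `prevalence_ncr`, by monotone bisection on a fixed Monte-Carlo draw of
#' the discrete-plus-continuous feature space.
#'
#' @param config A [sim_config()].
#' @param n_mc Monte-Carlo sample size for the feature draw (default 20000).
#' @param tol Prevalence tolerance for the bisection (default 1e-3).
#' @return The calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(config, n_mc = 20000, tol = 1e-3) {
  config <- validate_sim_config(unclass(config))
  seeds <- stage_seeds(config$seed, 5)
  x <- with_seed(seeds[1], draw_profiles(config, n_mc))
  eta_x <- drop(high_risk_indicators(x) %*% config$risk_coefficients)
  prev <- function(b0) mean(plogis(b0 + eta_x))
  lo <- -20; hi <- 20
  if (prev(lo) > config$prevalence_ncr || prev(hi) < config$prevalence_ncr) {
    abort("target prevalence unreachable under the configured coefficients")
  }
  while (TRUE) {
    mid <- (lo + hi) / 2
    p <- prev(mid)
    if (abs(p - config$prevalence_ncr) < tol || hi - lo < 1e-12) {
      return(mid)
    }
    if (p < config$prevalence_ncr) lo <- mid else hi <- mid
  }
}

#' Simulate the latent patient truth of a synthetic study cohort
#'
#' Draws per-patient staging features, the binary (near-)complete response
#' under the logistic risk link, the Mandard tumor regression grade (TRG)
#' conditional on response, the watch-and-wait surrogate pathway for a
#' configurable fraction of complete responders, and the CRT-to-surgery
#' interval (truncated normal).
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return Tibble, one row per patient: `patient_id`, the 7 staging features,
#'   `ncr` (logical), `trg` (integer 1-5, `NA` for watch-and-wait patients),
#'   `ww_sustained` (logical), `interval_weeks`.
#' @export
simulate_truth <- function(config, seed = config$seed) {
  config <- validate_sim_config(unclass(config))
  b0 <- if (is.null(config$intercept)) calibrate_intercept(config) else
    config$intercept
  seeds <- stage_seeds(seed, 5)
  n <- config$n_patients
  profiles <- with_seed(seeds[2], draw_profiles(config, n))
  with_seed(seeds[3], {
    eta <- b0 + drop(high_risk_indicators(profiles) %*%
                       config$risk_coefficients)
    ncr <- runif(n) < plogis(eta)
    trg <- integer(n)
    trg[ncr] <- as.integer(sample(names(config$trg_given_ncr), sum(ncr),
                                  replace = TRUE, prob = config$trg_given_ncr))
    trg[!ncr] <- as.integer(sample(names(config$trg_given_noncr), sum(!ncr),
                                   replace = TRUE,
                                   prob = config$trg_given_noncr))
    ww <- trg == 1L & runif(n) < config$ww_fraction_of_cr
    interval <- rnorm(n, config$interval_mean_weeks, config$interval_sd_weeks)
    while (any(interval < config$interval_min_weeks)) {
      bad <- interval < config$interval_min_weeks
      interval[bad] <- rnorm(sum(bad), config$interval_mean_weeks,
                             config$interval_sd_weeks)
    }
    out <- dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("P%04d", seq_len(n))),
      profiles
    )
    out$ncr <- ncr
    out$trg <- ifelse(ww, NA_integer_, trg)
    out$ww_sustained <- ww
    out$interval_weeks <- interval
    out
  })
}

#' Build the reader panel
#'
#' @param config A [sim_config()].
#' @return Tibble with `reader_id` and `stratum` (`"expert"`/`"nonexpert"`).
#' @export
reader_panel <- function(config) {
  config <- validate_sim_config(unclass(config))
  tibble::tibble(
    reader_id = sprintf("R%02d",
                        seq_len(config$n_expert_readers +
                                  config$n_nonexpert_readers)),
    stratum = rep(c("expert", "nonexpert"),
                  c(config$n_expert_readers, config$n_nonexpert_readers))
  )
}

# Perceive one binary feature through the asymmetric error channel.
perceive_binary <- function(truth, p_miss, p_false_call) {
  u <- runif(length(truth))
  ifelse(truth, u >= p_miss, u < p_false_call)
}

# Perceive the T-stage: with probability t_adjacent move to an adjacent
# category (direction uniform; boundaries move inward).
perceive_t_stage <- function(t_stage, t_adjacent) {
  idx <- match(t_stage, T_STAGE_LEVELS)
  n <- length(idx)
  move <- runif(n) < t_adjacent
  dir <- ifelse(runif(n) < 0.5, -1L, 1L)
  new <- idx + ifelse(move, dir, 0L)
  new <- pmin(pmax(new, 1L), length(T_STAGE_LEVELS))
  # a boundary draw that would leave the scale moves inward instead
  stuck <- move & new == idx
  new[stuck] <- idx[stuck] + ifelse(idx[stuck] == 1L, 1L, -1L)
  T_STAGE_LEVELS[new]
}

#' Simulate the readers' staging assessments of a cohort
#'
#' Passes each patient's true staging profile through every reader's
#' perception-error channel: binary features are missed with `p_miss` and
#' falsely called with `p_false_call` (misses dominate, encoding the
#' instruction to answer "no" when in doubt; experts err less than
#' non-experts), the T-stage is perturbed to an adjacent category with a
#' stratum-specific probability, and size carries multiplicative log-normal
#' noise. The 4-point booleans are derived from the same perceived features,
#' so each reader's assessment is internally consistent. All three scores
#' are computed from the perceived assessment.
#'
#' @param truth Cohort truth from [simulate_truth()].
#' @param panel Reader panel from [reader_panel()].
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return Long tibble, one row per reader x patient, with the perceived
#'   staging features, the four 4-point booleans, and the three score
#'   columns `five_point`, `four_point`, `two_point`.
#' @export
simulate_assessments <- function(truth, panel, config, seed = config$seed) {
  config <- validate_sim_config(unclass(config))
  if (nrow(panel) != config$n_expert_readers + config$n_nonexpert_readers) {
    abort("panel size does not match the configuration")
  }
  if (nrow(truth) != config$n_patients) {
    abort("truth size does not match the configuration")
  }
  seeds <- stage_seeds(seed, 5)
  with_seed(seeds[4], {
    grid <- tidyr::expand_grid(
      reader_id = panel$reader_id,
      patient_id = truth$patient_id
    )
    grid <- dplyr::left_join(grid, panel, by = "reader_id")
    truth_cols <- c("patient_id", "t_stage", "size_cm", "signal", "shape",
                    "n_stage", "emvi", "mrf")
    grid <- dplyr::left_join(grid, truth[truth_cols], by = "patient_id",
                             suffix = c("", ".true"))
    out <- purrr::map_dfr(c("expert", "nonexpert"), function(s) {
      g <- grid[grid$stratum == s, ]
      if (nrow(g) == 0) return(g)
      fe <- config$feature_error[[s]]
      g$t_stage <- perceive_t_stage(g$t_stage, fe$t_adjacent)
      g$size_cm <- g$size_cm *
        exp(rnorm(nrow(g), 0, fe$size_sdlog))
      g$signal <- ifelse(
        perceive_binary(g$signal == "heterogeneous", fe$p_miss,
                        fe$p_false_call),
        "heterogeneous", "homogeneous")
      g$shape <- ifelse(
        perceive_binary(g$shape == "irregular", fe$p_miss, fe$p_false_call),
        "irregular", "regular")
      n_pos <- perceive_binary(g$n_stage %in% c("n1", "n2"), fe$p_miss,
                               fe$p_false_call)
      g$n_stage <- dplyr::case_when(
        n_pos & g$n_stage %in% c("n1", "n2") ~ g$n_stage,
        n_pos ~ "n1",
        .default = "n0"
      )
      g$emvi <- perceive_binary(g$emvi, fe$p_miss, fe$p_false_call)
      g$mrf  <- perceive_binary(g$mrf, fe$p_miss, fe$p_false_call)
      g
    })
    out <- out[order(match(out$reader_id, panel$reader_id),
                     match(out$patient_id, truth$patient_id)), ]
    out$mrf_obvious   <- out$mrf
    out$t_high_risk   <- out$t_stage %in% c("t3c", "t3d", "t4")
    out$nodal_obvious <- out$n_stage %in% c("n1", "n2")
    out$emvi_obvious  <- out$emvi
    scored <- classify_features(out)
    scored$five_point <- five_point_score(scored$n_high, scored$n_low)
    scored$four_point <- four_point_score(scored$mrf_obvious,
                                          scored$t_high_risk,
                                          scored$nodal_obvious,
                                          scored$emvi_obvious)
    scored$two_point <- two_point_score(scored$t_stage, scored$mrf)
    keep <- c("patient_id", "reader_id", "stratum", "t_stage", "size_cm",
              "signal", "shape", "n_stage", "emvi", "mrf", "mrf_obvious",
              "t_high_risk", "nodal_obvious", "emvi_obvious",
              "five_point", "four_point", "two_point")
    tibble::as_tibble(scored[keep])
  })
}

#' Simulate a complete multireader study
#'
#' Convenience wrapper: truth, panel, assessments, and the long score table.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return List with tibbles `truth`, `panel`, `assessments`, `scores` and
#'   the resolved `config` (with the calibrated intercept filled in).
#' @export
simulate_study <- function(config = sim_config(), seed = config$seed) {
  config <- validate_sim_config(unclass(config))
  if (is.null(config$intercept)) {
    config$intercept <- calibrate_intercept(config)
  }
  truth <- simulate_truth(config, seed = seed)
  panel <- reader_panel(config)
  assessments <- simulate_assessments(truth, panel, config, seed = seed)
  scores <- tidyr::pivot_longer(
    assessments[c("patient_id", "reader_id", SCORE_METHODS)],
    cols = dplyr::all_of(SCORE_METHODS),
    names_to = "method", values_to = "score"
  )
  list(truth = truth, panel = panel, assessments = assessments,
       scores = scores, config = config)
}
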