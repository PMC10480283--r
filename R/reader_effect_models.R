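#' Per-observation correctness records
#'
#' Joins the long score table to the outcome labels and records, per reader
#' x patient x method, whether the reader's dichotomised prediction matched
#' the (near-)complete-response label.
#'
#' @param scores Long score table (`patient_id`, `reader_id`, `method`,
#'   `score`).
#' @param outcomes Outcome table with `patient_id` and logical `ncr`.
#' @param panel Reader panel (`reader_id`, `stratum`).
#' @return Tibble with `patient_id`, `reader_id`, `stratum`, `method`,
#'   `prediction`, `correct`.
#' @export
correctness_records <- function(scores, outcomes, panel) {
  df <- dplyr::inner_join(scores, outcomes[c("patient_id", "ncr")],
                          by = "patient_id")
  df <- dplyr::inner_join(df, panel, by = "reader_id")
  df <- df[!is.na(df$score), ]
  df$prediction <- dichotomize(df$method, df$score)
  df$correct <- df$prediction == df$ncr
  tibble::as_tibble(df[c("patient_id", "reader_id", "stratum", "method",
                         "ncr", "prediction", "correct")])
}

# Profile REML for the one-way random-intercept linear model
# y = X beta + b_patient + e, exploiting the block structure of
# V = sigma2_e (I + lambda J) per patient: closed-form GLS given lambda,
# one-dimensional optimisation of the REML criterion over log(lambda).
reml_random_intercept <- function(y, X, group) {
  n <- length(y)
  p <- ncol(X)
  if (sd(y) < .Machine$double.eps * 100) {
    abort("zero residual variance: correctness is constant, model undefined")
  }
  group <- as.factor(group)
  # per-group sufficient statistics: the profile criterion only needs
  # group sums, so each lambda evaluation is O(G), not O(n)
  xtx_full <- crossprod(X)
  xty_full <- drop(crossprod(X, y))
  yty_full <- sum(y^2)
  sx <- rowsum(X, group)
  sy <- drop(rowsum(y, group))
  m <- as.vector(table(group))
  gls_parts <- function(lambda) {
    c_i <- lambda / (1 + lambda * m)
    xtx <- xtx_full - crossprod(sx * c_i, sx)
    xty <- xty_full - drop(crossprod(sx, c_i * sy))
    yty <- yty_full - sum(c_i * sy^2)
    beta <- solve(xtx, xty)
    rss <- drop(yty - crossprod(beta, xty))
    list(beta = drop(beta), xtx = xtx, rss = rss,
         logdet = sum(log(1 + lambda * m)))
  }
  neg_reml <- function(log_lambda) {
    g <- gls_parts(exp(log_lambda))
    sigma2 <- g$rss / (n - p)
    0.5 * ((n - p) * log(sigma2) + g$logdet +
             as.numeric(determinant(g$xtx, logarithm = TRUE)$modulus))
  }
  opt <- optimize(neg_reml, interval = c(-15, 10))
  # compare the interior optimum with the lambda = 0 boundary
  lambda <- if (neg_reml(-30) <= opt$objective) 0 else exp(opt$minimum)
  g <- gls_parts(lambda)
  sigma2_e <- g$rss / (n - p)
  if (sigma2_e <= .Machine$double.eps * 100) {
    abort("zero residual variance: correctness is constant, model undefined")
  }
  vcov_beta <- sigma2_e * solve(g$xtx)
  list(beta = g$beta, vcov = vcov_beta, sigma2_patient = lambda * sigma2_e,
       sigma2_resid = sigma2_e, lambda = lambda)
}

#' Reader-experience effect via a random-intercept linear probability model
#'
#' Fits `correct ~ expert` as a linear probability model with a
#' patient-level random intercept, accounting for the repeated measurement
#' of each patient by the reader panel:
#' `correct_ij = b0 + b1 * expert_j + u_i + e_ij`, with
#' `u_i ~ (0, sigma2_patient)` and `e_ij ~ (0, sigma2_resid)`. Variance
#' components are estimated by REML, profiling the criterion over the
#' variance ratio with a closed-form GLS step; the experience effect `b1`
#' is the expert minus non-expert difference in correctness probability,
#' with Wald confidence interval and p-value.
#'
#' @param records Correctness records for one method (see
#'   [correctness_records()]): columns `patient_id`, `stratum`, `correct`.
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @return Object of class `reader_effect_fit` with elements `beta`
#'   (intercept and expert effect), `se`, `ci`, `p_value`,
#'   `sigma2_patient`, `sigma2_resid`, `icc`, `n_obs`, `n_patients`.
#'   [tidy()] and [glance()] methods are available.
#' @export
fit_random_intercept <- function(records, conf_level = 0.95) {
  if (length(unique(records$patient_id)) < 2) {
    abort("at least two patients are required")
  }
  for (s in c("expert", "nonexpert")) {
    if (length(unique(records$reader_id[records$stratum == s])) < 2) {
      abort(paste0("at least two readers are required in stratum '", s, "'"))
    }
  }
  y <- as.numeric(records$correct)
  X <- cbind(`(Intercept)` = 1, expert = as.numeric(records$stratum ==
                                                      "expert"))
  fit <- reml_random_intercept(y, X, records$patient_id)
  se <- sqrt(diag(fit$vcov))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      beta = setNames(fit$beta, colnames(X)),
      se = setNames(se, colnames(X)),
      ci = cbind(lower = fit$beta - z * se, upper = fit$beta + z * se),
      p_value = setNames(2 * pnorm(-abs(fit$beta / se)), colnames(X)),
      sigma2_patient = fit$sigma2_patient,
      sigma2_resid = fit$sigma2_resid,
      icc = fit$sigma2_patient / (fit$sigma2_patient + fit$sigma2_resid),
      conf_level = conf_level,
      n_obs = length(y),
      n_patients = length(unique(records$patient_id))
    ),
    class = "reader_effect_fit"
  )
}

#' @export
print.reader_effect_fit <- function(x, ...) {
  cat("Random-intercept linear probability model (profile REML)\n")
  cat(sprintf("  expert effect: %+.4f (%.0f%% CI %.4f to %.4f), p = %.3g\n",
              x$beta["expert"], 100 * x$conf_level, x$ci["expert", "lower"],
              x$ci["expert", "upper"], x$p_value["expert"]))
  cat(sprintf("  variance components: patient %.5f, residual %.5f (ICC %.3f)\n",
              x$sigma2_patient, x$sigma2_resid, x$icc))
  invisible(x)
}

#' @method tidy reader_effect_fit
#' @export
tidy.reader_effect_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$beta), estimate = unname(x$beta),
    std.error = unname(x$se),
    conf.low = unname(x$ci[, "lower"]), conf.high = unname(x$ci[, "upper"]),
    p.value = unname(x$p_value)
  )
}

#' @method glance reader_effect_fit
#' @export
glance.reader_effect_fit <- function(x, ...) {
  tibble::tibble(sigma2_patient = x$sigma2_patient,
                 sigma2_resid = x$sigma2_resid, icc = x$icc,
                 n_obs = x$n_obs, n_patients = x$n_patients)
}

# IRLS for binomial logistic regression on aggregated (successes, failures)
# counts; converges on the score (gradient) norm.
irls_logistic <- function(X, successes, failures, tol = 1e-8, max_iter = 100) {
  sizes <- successes + failures
  beta <- rep(0, ncol(X))
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    grad <- drop(crossprod(X, successes - sizes * mu))
    W <- sizes * mu * (1 - mu)
    info <- crossprod(X, X * W)
    if (rcond(info) < 1e-12 || any(abs(beta) > 30)) {
      abort(paste0("IRLS failed to converge (iteration ", iter, "): the ",
                   "fit is separating or the information matrix is singular"))
    }
    beta <- beta + solve(info, grad)
    if (sqrt(sum(grad^2)) < tol) {
      eta <- drop(X %*% beta)
      mu <- plogis(eta)
      W <- sizes * mu * (1 - mu)
      info <- crossprod(X, X * W)
      return(list(beta = beta, vcov = solve(info), n_iter = iter))
    }
  }
  abort("IRLS failed to converge within the iteration limit")
}

#' Interval-confounder model: correctness versus CRT-to-surgery interval
#'
#' Binomial logistic regression of the per-patient number of correct reader
#' diagnoses (out of the panel size) on the interval, in weeks, between the
#' end of chemoradiotherapy and surgery or watch-and-wait entry. Fitted by
#' iteratively reweighted least squares to a score-norm tolerance of 1e-8;
#' the slope is the per-week change in log-odds of a correct diagnosis,
#' with a Wald p-value.
#'
#' @param data Per-patient data frame with columns `n_correct`,
#'   `n_incorrect`, and `interval_weeks`.
#' @param conf_level Confidence level for the Wald intervals.
#' @return Object of class `interval_model_fit` with `beta` (intercept,
#'   slope), `se`, `ci`, `p_slope`, `n_iter`. [tidy()]/[glance()] available.
#' @export
fit_interval_model <- function(data, conf_level = 0.95) {
  needed <- c("n_correct", "n_incorrect", "interval_weeks")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(data$interval_weeks <= 0)) abort("intervals must be positive")
  prop <- data$n_correct / (data$n_correct + data$n_incorrect)
  if (all(prop %in% c(0, 1))) {
    abort(paste0("all per-patient proportions are 0 or 1: the binomial ",
                 "fit is degenerate (complete separation)"))
  }
  X <- cbind(`(Intercept)` = 1, interval_weeks = data$interval_weeks)
  fit <- irls_logistic(X, data$n_correct, data$n_incorrect)
  se <- sqrt(diag(fit$vcov))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      beta = setNames(fit$beta, colnames(X)),
      se = setNames(se, colnames(X)),
      ci = cbind(lower = fit$beta - z * se, upper = fit$beta + z * se),
      p_slope = unname(2 * pnorm(-abs(fit$beta[2] / se[2]))),
      conf_level = conf_level,
      n_iter = fit$n_iter,
      n_patients = nrow(data)
    ),
    class = "interval_model_fit"
  )
}

#' @export
print.interval_model_fit <- function(x, ...) {
  cat("Binomial regression of reader correctness on CRT-to-surgery interval\n")
  cat(sprintf("  slope: %+.4f log-odds per week (%.0f%% CI %.4f to %.4f), p = %.3g\n",
              x$beta[2], 100 * x$conf_level, x$ci[2, "lower"],
              x$ci[2, "upper"], x$p_slope))
  invisible(x)
}

#' @method tidy interval_model_fit
#' @export
tidy.interval_model_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$beta), estimate = unname(x$beta),
    std.error = unname(x$se),
    conf.low = unname(x$ci[, "lower"]), conf.high = unname(x$ci[, "upper"]),
    p.value = c(NA_real_, x$p_slope)
  )
}

#' @method glance interval_model_fit
#' @export
glance.interval_model_fit <- function(x, ...) {
  tibble::tibble(n_patients = x$n_patients, n_iter = x$n_iter,
                 p_slope = x$p_slope)
}

#' Per-patient correctness counts for the interval model
#'
#' Aggregates the correctness records of one method to per-patient counts of
#' correct and incorrect reader diagnoses and joins the CRT-to-surgery
#' interval.
#'
#' @param records Correctness records for one method.
#' @param outcomes Outcome table with `patient_id` and `interval_weeks`.
#' @return Tibble with `patient_id`, `n_correct`, `n_incorrect`,
#'   `interval_weeks`.
#' @export
interval_correctness <- function(records, outcomes) {
  agg <- dplyr::summarise(dplyr::group_by(records, .data$patient_id),
                          n_correct = sum(.data$correct),
                          n_incorrect = sum(!.data$correct),
                          .groups = "drop")
  dplyr::inner_join(agg, outcomes[c("patient_id", "interval_weeks")],
                    by = "patient_id")
}

#' Reader-experience effect table
#'
#' For each scoring method and diagnostic metric, fits the random-intercept
#' linear probability model on the relevant correctness subset and reports
#' the expert minus non-expert effect with its confidence interval and
#' p-value. Subsets: sensitivity uses (near-)complete responders only,
#' specificity uses non-responders only, accuracy uses all patients.
#'
#' @param records Correctness records across methods (see
#'   [correctness_records()]; must carry the `ncr` label column).
#' @param conf_level Confidence level for the Wald intervals.
#' @return Tibble with `method`, `metric`, `effect`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @export
experience_effect_table <- function(records, conf_level = 0.95) {
  methods <- intersect(SCORE_METHODS, unique(records$method))
  missing <- setdiff(SCORE_METHODS, methods)
  if (length(missing) > 0) {
    warn(paste0("methods absent from records, rows omitted: ",
                paste(missing, collapse = ", ")))
  }
  subsets <- list(
    sensitivity = function(df) df[df$ncr, ],
    specificity = function(df) df[!df$ncr, ],
    accuracy = function(df) df
  )
  purrr::map_dfr(methods, function(m) {
    df_m <- records[records$method == m, ]
    purrr::map_dfr(names(subsets), function(met) {
      fit <- tryCatch(
        fit_random_intercept(subsets[[met]](df_m), conf_level = conf_level),
        error = function(e) {
          warn(paste0("effect model for ", m, "/", met,
                      " is degenerate (", conditionMessage(e),
                      "); reporting NA"))
          NULL
        })
      if (is.null(fit)) {
        return(tibble::tibble(method = m, metric = met, effect = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              p_value = NA_real_))
      }
      tibble::tibble(
        method = m, metric = met,
        effect = unname(fit$beta["expert"]),
        ci_low = fit$ci["expert", "lower"],
        ci_high = fit$ci["expert", "upper"],
        p_value = unname(fit$p_value["expert"])
      )
    })
  })
}
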