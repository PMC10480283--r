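#' Patient-level oriented score vector for ROC analysis
#'
#' Averages the scores of a reader stratum per patient and orients the
#' result so that larger values mean a higher predicted probability of a
#' (near-)complete response: the 5-point confidence score is used as-is
#' (5 = highly likely responder); the 4-point and 2-point risk scores are
#' negated (they count high-risk features).
#'
#' @param scores Long score table (`patient_id`, `reader_id`, `method`,
#'   `score`).
#' @param method One of `"five_point"`, `"four_point"`, `"two_point"`.
#' @param readers Optional reader ids to restrict to (a stratum); default all.
#' @return Tibble with `patient_id`, `value` (oriented mean score),
#'   `n_readers`, and attributes `method` and `orientation`.
#' @export
orient_scores <- function(scores, method, readers = NULL) {
  if (!method %in% SCORE_METHODS) {
    abort(paste0("unknown scoring method: ", method))
  }
  sub <- scores[scores$method == method, ]
  if (!is.null(readers)) sub <- sub[sub$reader_id %in% readers, ]
  sub <- sub[!is.na(sub$score), ]
  out <- dplyr::summarise(dplyr::group_by(sub, .data$patient_id),
                          value = mean(.data$score),
                          n_readers = dplyr::n(), .groups = "drop")
  all_pat <- unique(scores$patient_id)
  missing <- setdiff(all_pat, out$patient_id)
  if (length(missing) > 0) {
    abort(paste0("patients without any ", method, " score: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  sign <- if (method == "five_point") 1 else -1
  out$value <- sign * out$value
  attr(out, "method") <- method
  attr(out, "orientation") <- if (sign == 1) "as-is" else "negated"
  out
}

#' Area under the ROC curve
#'
#' Computes the AUC of an oriented score against a binary outcome, either in
#' its Mann-Whitney form (the fraction of (positive, negative) patient pairs
#' in which the positive patient scores higher, ties counting one half) or
#' as the trapezoidal area under the empirical ROC curve. The two forms are
#' mathematically identical; both are provided so the identity can be
#' asserted.
#'
#' @param value Numeric score vector, oriented so larger = more likely
#'   positive.
#' @param outcome Logical (or 0/1) outcome vector; `TRUE` = positive class.
#' @param method `"mann_whitney"` (default) or `"trapezoid"`.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(3, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE))  # 0.875
#' @export
roc_auc <- function(value, outcome, method = c("mann_whitney", "trapezoid")) {
  method <- match.arg(method)
  outcome <- as.logical(outcome)
  stopifnot(length(value) == length(outcome), all(is.finite(value)))
  n_pos <- sum(outcome)
  n_neg <- sum(!outcome)
  if (n_pos == 0 || n_neg == 0) {
    abort("both outcome classes must be present to compute an AUC")
  }
  if (method == "mann_whitney") {
    r <- rank(value, ties.method = "average")
    (sum(r[outcome]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  } else {
    roc <- roc_points(value, outcome)
    sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  }
}

# Empirical ROC curve: one operating point per distinct threshold, with the
# convention that a score strictly greater than the threshold is called
# positive. Rows ordered from (0,0) to (1,1).
roc_points <- function(value, outcome) {
  outcome <- as.logical(outcome)
  thr <- sort(unique(value), decreasing = TRUE)
  n_pos <- sum(outcome)
  n_neg <- sum(!outcome)
  tpr <- vapply(thr, function(t) sum(value >= t & outcome) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(value >= t & !outcome) / n_neg,
                numeric(1))
  tibble::tibble(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
}

#' Stratified percentile bootstrap confidence interval for the AUC
#'
#' Resamples patients with replacement within each outcome class (so every
#' resample contains both classes) and returns the percentile interval of
#' the resampled AUCs.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap resamples (at least 500; default 2000).
#' @param conf_level Interval coverage (default 0.95).
#' @param seed Seed for the resampling.
#' @return Numeric vector `c(lower, upper)`.
#' @export
auc_bootstrap_ci <- function(value, outcome, n_boot = 2000, conf_level = 0.95,
                             seed = 1L) {
  if (n_boot < 500) abort("n_boot must be at least 500")
  outcome <- as.logical(outcome)
  pos <- which(outcome)
  neg <- which(!outcome)
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both outcome classes must be present")
  }
  aucs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      roc_auc(value[idx], outcome[idx])
    }, numeric(1))
  })
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  unname(quantile(aucs, probs, type = 7))
}

#' Youden-optimal cutoff on an oriented score
#'
#' Finds the threshold maximising the Youden index J = sensitivity +
#' specificity - 1, searching the midpoints between consecutive distinct
#' score values (plus outer sentinels). Scores strictly greater than the
#' threshold are called positive. Ties in J are broken in favour of higher
#' specificity, then of the higher threshold.
#'
#' @inheritParams roc_auc
#' @return A one-row tibble: `cutoff`, `youden_j`, `sensitivity`,
#'   `specificity`.
#' @export
optimal_cutoff <- function(value, outcome) {
  outcome <- as.logical(outcome)
  if (!any(outcome) || all(outcome)) {
    abort("both outcome classes must be present")
  }
  v <- sort(unique(value))
  cand <- c(v[1] - 1, (head(v, -1) + tail(v, -1)) / 2, v[length(v)] + 1)
  stats_at <- purrr::map_dfr(cand, function(t) {
    pred <- value > t
    tibble::tibble(
      cutoff = t,
      sensitivity = sum(pred & outcome) / sum(outcome),
      specificity = sum(!pred & !outcome) / sum(!outcome)
    )
  })
  stats_at$youden_j <- stats_at$sensitivity + stats_at$specificity - 1
  best <- dplyr::arrange(stats_at, dplyr::desc(.data$youden_j),
                         dplyr::desc(.data$specificity),
                         dplyr::desc(.data$cutoff))[1, ]
  best[c("cutoff", "youden_j", "sensitivity", "specificity")]
}

#' Confusion-matrix metrics
#'
#' Sensitivity, specificity, positive and negative predictive value, and
#' accuracy from confusion counts, with the positive class being a
#' (near-)complete response. Ratios with a zero denominator are reported as
#' `NA`, never as 0.
#'
#' @param tp,fp,fn,tn Non-negative integer counts (vectorised).
#' @return Tibble with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`.
#' @examples
#' confusion_metrics(tp = 3, fp = 1, fn = 1, tn = 5)
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- cbind(tp, fp, fn, tn)
  if (any(counts < 0)) abort("confusion counts must be non-negative")
  if (any(rowSums(counts) == 0)) abort("all confusion counts are zero")
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tibble::tibble(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    accuracy = (tp + tn) / (tp + fp + fn + tn)
  )
}

# Confusion counts of one reader's dichotomised predictions.
confusion_counts <- function(prediction, outcome) {
  tibble::tibble(
    tp = sum(prediction & outcome), fp = sum(prediction & !outcome),
    fn = sum(!prediction & outcome), tn = sum(!prediction & !outcome)
  )
}

#' Diagnostic-performance report by method and reader stratum
#'
#' For each scoring method and reader stratum (all readers, experts,
#' non-experts): the confusion-matrix metrics at the method's fixed
#' dichotomisation (each reader's predictions scored against the outcome,
#' then macro-averaged across the stratum's readers) and the AUC of the
#' stratum-mean oriented score with a stratified percentile bootstrap CI.
#'
#' @param scores Long score table.
#' @param outcomes Outcome table with `patient_id` and logical `ncr`.
#' @param panel Reader panel (`reader_id`, `stratum`).
#' @param n_boot,conf_level,seed Bootstrap settings for the AUC CI.
#' @return Tibble of class `diagnostic_report`: one row per method x
#'   stratum with `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`,
#'   `auc`, `auc_ci_low`, `auc_ci_high`, `n_readers`, `n_patients`.
#' @export
performance_table <- function(scores, outcomes, panel, n_boot = 2000,
                              conf_level = 0.95, seed = 1L) {
  strata <- list(all = unique(panel$reader_id))
  for (s in c("expert", "nonexpert")) {
    ids <- panel$reader_id[panel$stratum == s]
    if (length(ids) == 0) {
      warn(paste0("no readers in stratum '", s, "'; row omitted"))
    } else {
      strata[[s]] <- ids
    }
  }
  methods <- intersect(SCORE_METHODS, unique(scores$method))
  lab <- setNames(outcomes$ncr, outcomes$patient_id)
  rows <- purrr::map_dfr(methods, function(m) {
    purrr::map_dfr(names(strata), function(s) {
      sub <- scores[scores$method == m &
                      scores$reader_id %in% strata[[s]] &
                      !is.na(scores$score), ]
      per_reader <- purrr::map_dfr(split(sub, sub$reader_id), function(r) {
        pred <- dichotomize(m, r$score)
        cc <- confusion_counts(pred, lab[r$patient_id])
        confusion_metrics(cc$tp, cc$fp, cc$fn, cc$tn)
      })
      avg <- dplyr::summarise(per_reader,
                              dplyr::across(dplyr::everything(),
                                            ~ mean(.x, na.rm = TRUE)))
      v <- orient_scores(scores, m, readers = strata[[s]])
      outcome <- lab[v$patient_id]
      auc_hat <- roc_auc(v$value, outcome)
      ci <- auc_bootstrap_ci(v$value, outcome, n_boot = n_boot,
                             conf_level = conf_level, seed = seed)
      dplyr::bind_cols(
        tibble::tibble(method = m, stratum = s),
        avg,
        tibble::tibble(auc = auc_hat, auc_ci_low = ci[1], auc_ci_high = ci[2],
                       n_readers = length(unique(sub$reader_id)),
                       n_patients = length(unique(sub$patient_id)))
      )
    })
  })
  class(rows) <- c("diagnostic_report", class(rows))
  attr(rows, "settings") <- list(
    n_boot = n_boot, conf_level = conf_level, seed = seed,
    cutoffs = c(five_point = "positive if score >= 4",
                four_point = "positive if score <= 1",
                two_point = "positive if score == 0"),
    orientation = c(five_point = "as-is", four_point = "negated",
                    two_point = "negated")
  )
  rows
}

#' Paired bootstrap comparison of two AUCs
#'
#' Two-sided p-value for the difference in AUC between two oriented score
#' vectors over the same patients: patients are resampled with replacement
#' (stratified within outcome class), both AUCs recomputed on each
#' resample, and the p-value read off the bootstrap distribution of the
#' difference against zero.
#'
#' @param value1,value2 Oriented score vectors over the same patients (same
#'   order).
#' @param outcome Logical outcome vector.
#' @param n_boot,seed Bootstrap settings.
#' @return List with `delta_auc` (observed difference), `p_value`, `n_boot`.
#' @export
compare_aucs <- function(value1, value2, outcome, n_boot = 2000, seed = 1L) {
  if (length(value1) != length(value2) ||
      length(value1) != length(outcome)) {
    abort("value1, value2 and outcome must cover the same patients")
  }
  outcome <- as.logical(outcome)
  pos <- which(outcome)
  neg <- which(!outcome)
  deltas <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      roc_auc(value1[idx], outcome[idx]) - roc_auc(value2[idx], outcome[idx])
    }, numeric(1))
  })
  p <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  list(delta_auc = roc_auc(value1, outcome) - roc_auc(value2, outcome),
       p_value = min(p, 1), n_boot = n_boot)
}
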