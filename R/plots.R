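#' ROC curves of the reader-averaged scores
#'
#' Plots the empirical ROC curve of the patient-level mean oriented score
#' for each scoring method (all readers, or a supplied reader subset).
#'
#' @param scores Long score table.
#' @param outcomes Outcome table with `patient_id` and logical `ncr`.
#' @param readers Optional reader ids to restrict to.
#' @param methods Scoring methods to include (default all three).
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, outcomes, readers = NULL,
                     methods = c("five_point", "four_point", "two_point")) {
  lab <- setNames(outcomes$ncr, outcomes$patient_id)
  curves <- purrr::map_dfr(methods, function(m) {
    v <- orient_scores(scores, m, readers = readers)
    pts <- roc_points(v$value, lab[v$patient_id])
    pts$method <- m
    pts$auc <- roc_auc(v$value, lab[v$patient_id])
    pts
  })
  curves$label <- sprintf("%s (AUC %.2f)", curves$method, curves$auc)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL,
                  title = "Prediction of (near-)complete response") +
    ggplot2::theme_minimal()
}

#' @describeIn performance_table Plot method: AUC with bootstrap CI per
#'   method and reader stratum.
#' @param object A `diagnostic_report` from [performance_table()].
#' @param ... Unused.
#' @method autoplot diagnostic_report
#' @export
autoplot.diagnostic_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$method, y = .data$auc,
                                       colour = .data$stratum)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$auc_ci_low, ymax = .data$auc_ci_high),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "AUC (95% bootstrap CI)", x = NULL, colour = "Readers") +
    ggplot2::theme_minimal()
}

#' Plot an interobserver-agreement report
#'
#' Dot plot of Krippendorff's alpha by item (scoring method or 4-point
#' feature) and reader stratum, with CIs when present.
#'
#' @param agreement Output of [agreement_table()].
#' @return A ggplot object.
#' @export
plot_agreement <- function(agreement) {
  p <- ggplot2::ggplot(agreement,
                       ggplot2::aes(x = .data$item, y = .data$alpha,
                                    colour = .data$stratum)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4),
                        size = 2)
  if (all(c("ci_low", "ci_high") %in% names(agreement)) &&
      any(!is.na(agreement$ci_low))) {
    p <- p + ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.4))
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(y = "Krippendorff's alpha", x = NULL, colour = "Readers") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
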