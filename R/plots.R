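#' Plot an evaluation result
#'
#' ROC, precision-over-threshold, or enrichment view of a `pp_eval`.
#'
#' @param object a [evaluate_predictions()] result.
#' @param type `"roc"`, `"enrichment"`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.pp_eval <- function(object, type = c("roc", "enrichment"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey60") +
      ggplot2::coord_equal() +
      ggplot2::labs(
        x = "false positive rate", y = "true positive rate",
        title = sprintf("ROC (%s), AUC = %s", object$score_col,
                        ifelse(is.na(object$auc), "NA",
                               sprintf("%.3f", object$auc)))
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$enrichment,
                    ggplot2::aes(x = .data$frac_screened, y = .data$frac_found)) +
      ggplot2::geom_line(linewidth = 0.8, colour = "#31a354") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey60") +
      ggplot2::labs(x = "fraction of ranked list examined",
                    y = "fraction of positives recovered",
                    title = sprintf("Enrichment (%s)", object$score_col)) +
      ggplot2::theme_minimal()
  }
}

#' Cross-validation metrics of a meta-classifier
#'
#' One point per fold for precision, recall and AUC.
#'
#' @param object a [train_meta_classifier()] model.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.pp_meta_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$cv, c("precision", "recall", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, colour = "#2c7fb8") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s meta-classifier, %d-fold CV",
                                  if (object$use_compound_id) "id-aware"
                                  else "anonymous", nrow(object$cv))) +
    ggplot2::theme_minimal()
}

#' Score distributions of a prediction run
#'
#' Histograms of the raw score, global Z and local Z over all prediction
#' rows — a quick sanity view of a run (the global Z panel should look
#' standardized; heavy right tails in raw score hint at promiscuous
#' targets).
#'
#' @param predictions prediction tibble from [predict_all()].
#' @return a ggplot object.
#' @export
plot_score_distributions <- function(predictions) {
  long <- tidyr::pivot_longer(
    predictions[, c("score", "global_z", "local_z")],
    dplyr::everything(), names_to = "which", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "#2c7fb8", colour = "white") +
    ggplot2::facet_wrap(~which, scales = "free") +
    ggplot2::labs(x = NULL, y = "predictions") +
    ggplot2::theme_minimal()
}
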