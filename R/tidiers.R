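#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-fold details of a fitted LOOCV model
#'
#' @param x An `sdc_model` from [loocv_evaluate()].
#' @param ... Unused.
#' @return A tibble with one row per leave-one-out fold: held-out subject,
#'   its group, the prediction and decision value, the tuned `C` and
#'   `gamma`, and the fold's feature count.
#' @method tidy sdc_model
#' @export
tidy.sdc_model <- function(x, ...) {
  dplyr::left_join(x$predictions, x$folds, by = "subject_id")
}

#' One-row summary of a fitted LOOCV model
#'
#' @param x An `sdc_model` from [loocv_evaluate()].
#' @param ... Unused.
#' @return A one-row tibble: model name and family, mean feature count
#'   across folds, confusion-matrix cells, accuracy, sensitivity,
#'   specificity and AUC.
#' @method glance sdc_model
#' @export
glance.sdc_model <- function(x, ...) {
  tibble::tibble(
    model = x$model_name,
    family = x$family,
    n_features_mean = mean(x$folds$n_features),
    tn = x$confusion[["tn"]], fp = x$confusion[["fp"]],
    fn = x$confusion[["fn"]], tp = x$confusion[["tp"]],
    accuracy = x$metrics$accuracy,
    sensitivity = x$metrics$sensitivity,
    specificity = x$metrics$specificity,
    auc = x$auc
  )
}

#' ROC curve plot for a fitted LOOCV model
#'
#' @param object An `sdc_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sdc_model
#' @export
autoplot.sdc_model <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = object$model_name,
      subtitle = sprintf("AUC = %.3f", object$auc),
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)") +
    ggplot2::theme_minimal()
}

#' Accuracy of all models by family
#'
#' @param summary A model-summary tibble from [evaluate_models()] (rows
#'   from several families may be bound together).
#' @return A ggplot object: accuracy per model, grouped by family.
#' @export
plot_model_accuracy <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$family, y = .data$accuracy,
                               colour = .data$family)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "LOOCV accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Significant-connection counts per region
#'
#' @param profile A tibble from [region_connection_profile()] or
#'   [subregion_profile()] (first column: unit; `n_connections`).
#' @return A ggplot object.
#' @export
plot_region_profile <- function(profile) {
  unit <- names(profile)[1]
  profile <- dplyr::arrange(profile, .data$n_connections)
  profile[[unit]] <- factor(profile[[unit]], levels = profile[[unit]])
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$n_connections,
                               y = .data[[unit]])) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "Significant connections", y = NULL) +
    ggplot2::theme_minimal()
}

#' Group comparison of weighted node degree
#'
#' @param degcmp A tibble from [compare_subregion_degrees()].
#' @return A ggplot object: SD and HC mean degree per subregion, with
#'   subregions showing a significant difference marked.
#' @export
plot_degree_comparison <- function(degcmp) {
  long <- tidyr::pivot_longer(degcmp, c("mean_degree_sd", "mean_degree_hc"),
                              names_to = "group", values_to = "degree")
  long$group <- ifelse(long$group == "mean_degree_sd", "SD", "HC")
  sig <- degcmp[degcmp$direction != "ns", ]
  p <- ggplot2::ggplot(long,
         ggplot2::aes(x = .data$subregion, y = .data$degree,
                      fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Weighted node degree", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(subregion = sig$subregion,
                            degree = pmax(sig$mean_degree_sd,
                                          sig$mean_degree_hc) * 1.05,
                            group = "SD"),
      shape = 8, show.legend = FALSE)
  }
  p
}
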