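#' Plot the objective trace of a fitted model
#'
#' One point per block update, colored by block, showing the monotone
#' decrease of the joint objective across inner and outer sweeps.
#'
#' @param object An `mcgl_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mcgl_fit
#' @export
autoplot.mcgl_fit <- function(object, ...) {
  df <- object$objective_trace |>
    dplyr::mutate(update = dplyr::row_number())
  ggplot2::ggplot(df,
    ggplot2::aes(x = .data$update, y = .data$objective,
      color = .data$block)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "block update", y = "objective value",
      color = "block",
      title = "Consensus graph learning: objective trace") +
    ggplot2::theme_minimal()
}

#' Plot cross-validation results
#'
#' For pooled schemes (LOOCV, k-fold) draws the ROC curve with the AUC in
#' the subtitle; for leave-one-disease-out draws the distribution of
#' per-disease AUC values.
#'
#' @param object An `mcgl_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mcgl_eval
#' @export
autoplot.mcgl_eval <- function(object, ...) {
  if (object$scheme == "lodocv") {
    ggplot2::ggplot(object$per_disease_auc, ggplot2::aes(x = .data$auc)) +
      ggplot2::geom_histogram(bins = 20, fill = "steelblue",
        color = "white") +
      ggplot2::labs(x = "per-disease AUC", y = "diseases",
        title = "Leave-one-disease-out AUC distribution") +
      ggplot2::theme_minimal()
  } else {
    pts <- roc_points(object$scores$score, object$scores$label)
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
        color = "grey60") +
      ggplot2::geom_line(color = "steelblue") +
      ggplot2::labs(x = "false positive rate", y = "true positive rate",
        title = sprintf("ROC (%s)", object$scheme),
        subtitle = sprintf("AUC = %.4f", object$auc_overall)) +
      ggplot2::theme_minimal()
  }
}

#' Heatmap of a learned consensus graph
#'
#' @param fit An `mcgl_fit` object.
#' @param side `"disease"` or `"lncrna"`.
#' @return A ggplot object.
#' @export
plot_consensus_graph <- function(fit, side = c("disease", "lncrna")) {
  side <- match.arg(side)
  S <- if (side == "disease") fit$SD else fit$SL
  df <- tibble::as_tibble(as.data.frame(as.table(S)),
    .name_repair = ~c("row", "col", "weight"))
  ggplot2::ggplot(df,
    ggplot2::aes(x = .data$col, y = .data$row, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
      title = sprintf("Learned %s consensus graph", side)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
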