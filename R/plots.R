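# ggplot2 visualisations for fitted and evaluated objects.

#' @describeIn train Autoplot method: training and validation curves.
#' @param object A `pet_trained_model`.
#' @method autoplot pet_trained_model
#' @export
autoplot.pet_trained_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = c("split", "metric"), names_sep = "_")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}

#' @describeIn kfold_cv Autoplot method: accuracy vs k with CI ribbons.
#' @param object A `pet_cv`.
#' @param ... Unused.
#' @method autoplot pet_cv
#' @export
autoplot.pet_cv <- function(object, ...) {
  s <- tidyr::pivot_longer(object$summary, cols = c("train_acc", "val_acc"),
                           names_to = "split", values_to = "acc")
  s$ci <- ifelse(s$split == "train_acc", object$summary$train_ci[
    match(s$k, object$summary$k)], object$summary$val_ci[
      match(s$k, object$summary$k)])
  ggplot2::ggplot(s, ggplot2::aes(.data$k, .data$acc, colour = .data$split)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$acc - .data$ci,
                                      ymax = .data$acc + .data$ci,
                                      fill = .data$split),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "folds (k)", y = "accuracy", colour = NULL, fill = NULL)
}

#' @describeIn roc_analysis Autoplot method: one-vs-rest ROC curves.
#' @param object A `pet_roc`.
#' @method autoplot pet_roc
#' @export
autoplot.pet_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc_points,
                  ggplot2::aes(.data$fpr, .data$tpr, colour = .data$class)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("macro AUC = %.3f", object$macro_auc))
}

#' Plot a 2D feature embedding
#'
#' @param embedding Tibble from [embed_2d()] or [joint_embedding()].
#' @param labels Optional point labels (e.g. classes) mapped to colour.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, labels = NULL) {
  d <- embedding
  if (!is.null(labels)) d$label <- labels
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$dim1, .data$dim2))
  if (!is.null(labels))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$label))
  else p <- p + ggplot2::geom_point()
  if ("external" %in% names(d))
    p <- p + ggplot2::geom_point(data = d[d$external, ], shape = 21,
                                 size = 3, colour = "red", fill = NA)
  p + ggplot2::labs(x = "dim 1", y = "dim 2", colour = NULL)
}

#' @describeIn project_mosaic Autoplot method: the blended heatmap mosaic.
#' @param object A `pet_class_heatmap`.
#' @param ... Unused.
#' @method autoplot pet_class_heatmap
#' @export
autoplot.pet_class_heatmap <- function(object, ...) {
  m <- object$overlay
  d <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d$value <- as.numeric(m[cbind(d$row, d$col)])
  ggplot2::ggplot(d, ggplot2::aes(.data$col, -.data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "response")
}
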