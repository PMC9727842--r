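# broom-style tidiers for fitted and evaluated objects.

#' @describeIn train Tidy method: the per-epoch training history.
#' @param x A `pet_trained_model`.
#' @param ... Unused.
#' @method tidy pet_trained_model
#' @export
tidy.pet_trained_model <- function(x, ...) x$history

#' @describeIn train Glance method: one-row fit summary.
#' @method glance pet_trained_model
#' @export
glance.pet_trained_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    kind = x$kind,
    n_classes = x$spec$n_classes,
    epochs_run = x$stopped_epoch,
    best_epoch = x$best_epoch,
    early_stopped = x$stopped_epoch < x$config$max_epochs,
    train_acc = last$train_acc,
    val_acc = last$val_acc,
    val_loss = last$val_loss)
}

#' @describeIn kfold_cv Tidy method: one row per k/round/fold.
#' @param x A `pet_cv`.
#' @param ... Unused.
#' @method tidy pet_cv
#' @export
tidy.pet_cv <- function(x, ...) x$folds

#' @describeIn kfold_cv Glance method: the per-k summary with 95% CIs.
#' @method glance pet_cv
#' @export
glance.pet_cv <- function(x, ...) x$summary

#' @describeIn roc_analysis Tidy method: the ROC curve points.
#' @param x A `pet_roc`.
#' @param ... Unused.
#' @method tidy pet_roc
#' @export
tidy.pet_roc <- function(x, ...) x$roc_points

#' @describeIn roc_analysis Glance method: per-class AUCs and the macro AUC.
#' @method glance pet_roc
#' @export
glance.pet_roc <- function(x, ...) {
  out <- tidyr::pivot_wider(x$auc, names_from = "class", values_from = "auc",
                            names_prefix = "auc_")
  out$macro_auc <- x$macro_auc
  out
}

#' @describeIn predict_external Tidy method: the per-case prediction table.
#' @param x A `pet_robustness`.
#' @param ... Unused.
#' @method tidy pet_robustness
#' @export
tidy.pet_robustness <- function(x, ...) x$cases

#' @describeIn predict_external Glance method: the predicted-label histogram.
#' @method glance pet_robustness
#' @export
glance.pet_robustness <- function(x, ...) {
  tidyr::pivot_wider(x$histogram, names_from = "predicted",
                     values_from = "n", names_prefix = "n_")
}
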