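# Out-of-distribution sensitivity: labels assigned to external dementia-type
# cases under the closed training vocabulary, and joint embedding cohesion.

#' Predict in-vocabulary labels for external cases
#'
#' Every external case receives exactly one label from the model's training
#' vocabulary (closed-set classification); the full probability vector is
#' recorded.
#'
#' @param model Trained classifier (e.g. the 4-class 3D model).
#' @param external_volumes Preprocessed external inputs (list of volumes, or a
#'   feature matrix for head models).
#' @param ids Optional case identifiers.
#' @return A list of class `pet_robustness`: `cases` (tibble with one row per
#'   case: id, predicted label, per-class probabilities) and `histogram`
#'   (tibble label/n, summing to the number of external cases).
#' @export
predict_external <- function(model, external_volumes, ids = NULL) {
  n <- n_inputs(external_volumes)
  if (n == 0) {
    message("no external cases")
    empty <- tibble::tibble(case = character(), predicted = character())
    return(structure(list(cases = empty,
                          histogram = tibble::tibble(predicted = character(),
                                                     n = integer())),
                     class = "pet_robustness"))
  }
  p <- predict_proba(model, external_volumes)
  lab <- predict_labels(model, external_volumes)
  ids <- ids %||% names(external_volumes) %||% sprintf("ext_%02d", seq_len(n))
  cases <- tibble::tibble(case = ids, predicted = lab)
  probs <- tibble::as_tibble(p, .name_repair = "minimal")
  names(probs) <- paste0("p_", colnames(p))
  cases <- dplyr::bind_cols(cases, probs)
  structure(list(cases = cases,
                 histogram = dplyr::count(cases, .data$predicted)),
            class = "pet_robustness")
}

#' Joint 2D embedding of training and external features
#'
#' One unsupervised embedding ([embed_2d()]) fitted on the concatenation of
#' training and external feature rows; external rows are flagged so their
#' placement relative to the training distribution can be examined.
#'
#' @param train_features,external_features Feature matrices with equal column
#'   count; at least 10 training rows.
#' @param seed Embedding seed.
#' @return Tibble with `dim1`, `dim2`, `external` (logical).
#' @export
joint_embedding <- function(train_features, external_features, seed = 1L) {
  train_features <- as.matrix(train_features)
  external_features <- as.matrix(external_features)
  if (nrow(train_features) < 10)
    stop("need >= 10 training rows", call. = FALSE)
  if (ncol(train_features) != ncol(external_features))
    stop(sprintf("feature dimension mismatch (%d vs %d)",
                 ncol(train_features), ncol(external_features)), call. = FALSE)
  emb <- embed_2d(rbind(train_features, external_features), seed = seed)
  emb$external <- c(rep(FALSE, nrow(train_features)),
                    rep(TRUE, nrow(external_features)))
  emb
}

#' Cohesion of external cases in an embedding
#'
#' Ratio of the mean pairwise distance among external cases to the mean
#' distance from external to training cases. Values below 1 mean the external
#' cases sit closer to each other than to the training cloud (grouped, not
#' scattered); the statistic is invariant to a global rescaling of the
#' coordinates.
#'
#' @param coordinates Numeric matrix or tibble of 2D coordinates.
#' @param external Logical flag vector (at least 2 external cases).
#' @return Nonnegative scalar.
#' @export
cohesion_statistic <- function(coordinates, external) {
  coordinates <- as.matrix(coordinates[, 1:2])
  external <- as.logical(external)
  if (sum(external) < 2)
    stop("need at least 2 external cases", call. = FALSE)
  ext <- coordinates[external, , drop = FALSE]
  trn <- coordinates[!external, , drop = FALSE]
  intra <- mean(dist(ext))
  cross <- mean(sqrt(pmax(outer(rowSums(ext^2), rowSums(trn^2), `+`) -
                            2 * ext %*% t(trn), 0)))
  if (cross == 0) return(0)
  intra / cross
}
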