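# Frozen-backbone transfer learning: backbone contract, deterministic
# stand-in extractor, and the trainable classification head.

#' Deterministic stand-in backbone
#'
#' A small frozen random-weight convolutional feature extractor over mosaic
#' images, standing behind the same contract as an ImageNet backbone: frozen
#' weights, identical input gives identical features, fixed feature length.
#' The mosaic is block-averaged onto a coarse grid, passed through a random
#' 3x3 convolution with ReLU, flattened and projected through a random tanh
#' layer.
#'
#' @param seed Seed for the frozen random weights.
#' @param feature_dim Length of the emitted feature vector.
#' @param pool_grid Coarse pooling grid (rows, cols).
#' @param n_filters Number of random convolution filters.
#' @return An object of class `pet_backbone`.
#' @export
standin_backbone <- function(seed = 1L, feature_dim = 256L,
                             pool_grid = c(16L, 16L), n_filters = 8L) {
  pool_grid <- as.integer(pool_grid)
  weights <- with_seed(seed, list(
    K = matrix(rnorm(9 * n_filters, 0, 0.5), 9, n_filters),
    W = matrix(rnorm(prod(pool_grid) * n_filters * feature_dim, 0,
                     1 / sqrt(prod(pool_grid) * n_filters)),
               prod(pool_grid) * n_filters, feature_dim),
    b = rnorm(feature_dim, 0, 0.1)))
  structure(list(name = sprintf("standin-%d", as.integer(seed)),
                 feature_dim = as.integer(feature_dim),
                 pool_grid = pool_grid, n_filters = as.integer(n_filters),
                 weights = weights, seed = as.integer(seed)),
            class = "pet_backbone")
}

block_pool <- function(m, grid) {
  gi <- ceiling(seq_len(nrow(m)) * grid[1] / nrow(m))
  gj <- ceiling(seq_len(ncol(m)) * grid[2] / ncol(m))
  sums <- rowsum(t(rowsum(m, gi)), gj)       # grid_cols x grid_rows
  counts <- tabulate(gi, grid[1]) %o% tabulate(gj, grid[2])
  t(sums) / counts
}

conv2d_same3 <- function(m, K) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  cols <- matrix(0, H * W, 9)
  k <- 1
  for (dj in 0:2) for (di in 0:2) {
    cols[, k] <- as.numeric(pad[di + seq_len(H), dj + seq_len(W)])
    k <- k + 1
  }
  cols %*% K
}

#' Frozen features of mosaic images
#'
#' @param backbone A `pet_backbone`.
#' @param mosaics A single mosaic matrix (or HxWx3 array with replicated
#'   channels) or a list of them.
#' @return Numeric matrix `n x feature_dim`; bit-identical for identical
#'   inputs (the backbone is frozen).
#' @export
backbone_features <- function(backbone, mosaics) {
  if (!is.list(mosaics)) mosaics <- list(mosaics)
  rows <- lapply(mosaics, function(m) {
    if (length(dim(m)) == 3) m <- apply(m, c(1, 2), mean)
    g <- block_pool(m, backbone$pool_grid)
    a <- pmax(conv2d_same3(g, backbone$weights$K), 0)
    tanh(as.numeric(a) %*% backbone$weights$W + backbone$weights$b)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(mosaics)
  out
}

#' Build a transfer-learning classifier head
#'
#' A fully connected head (dense, ReLU, dropout, softmax) consuming frozen
#' backbone features. Only the head is trainable; the backbone never changes.
#' Train it with [train()] on feature matrices from [backbone_features()].
#'
#' @param backbone A `pet_backbone` (or any list with `name` and
#'   `feature_dim`).
#' @param n_classes Number of output classes.
#' @param head_hidden Hidden width of the head.
#' @param dropout Dropout rate.
#' @param seed Weight-initialisation seed.
#' @return An untrained `pet_model` (kind `"mlp"`).
#' @export
build_tl_classifier <- function(backbone, n_classes, head_hidden = 64L,
                                dropout = 0.5, seed = 1L) {
  build_mlp(backbone$feature_dim, head_hidden, n_classes, dropout, seed,
            backbone_name = backbone$name)
}

#' @export
print.pet_model <- function(x, ...) {
  cat(sprintf("<pet_model: %s, %d classes%s>\n", x$kind, x$spec$n_classes,
              if (!is.null(x$classes))
                paste0(" (", paste(x$classes, collapse = ", "), ")") else ""))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs (best val epoch %d, val acc %.3f)\n",
                x$stopped_epoch, x$best_epoch,
                x$history$val_acc[nrow(x$history)]))
  invisible(x)
}

#' Learner factory for cross-validation
#'
#' Wraps a model builder and training protocol into the learner interface used
#' by [kfold_cv()]: a function `(x_tr, y_tr, x_val, y_val, seed)` returning a
#' trained model.
#'
#' @param spec A `pet_model_spec` (for the 3D model) or `NULL` with `backbone`
#'   set (for a transfer-learning head on feature matrices).
#' @param config A `pet_training_config`.
#' @param backbone Optional `pet_backbone`; when given, inputs are expected to
#'   be feature matrices already.
#' @return A learner function.
#' @export
cnn_learner <- function(spec, config = training_config(), backbone = NULL) {
  force(spec); force(config); force(backbone)
  function(x_tr, y_tr, x_val, y_val, seed = config$seed) {
    n_cls <- length(unique(c(as.character(y_tr), as.character(y_val))))
    model <- if (is.null(backbone)) {
      sp <- spec; sp$n_classes <- n_cls
      build_3d_model(sp, seed = seed)
    } else {
      build_tl_classifier(backbone, n_cls, seed = seed)
    }
    cfg <- config; cfg$seed <- as.integer(seed)
    train(model, x_tr, y_tr, x_val, y_val, cfg)
  }
}

#' Save / load a model checkpoint
#'
#' The weights go into a single binary checkpoint; a JSON sidecar
#' (`<path>.json`) records the architecture spec, training configuration,
#' classes and seeds so a checkpoint is self-describing.
#'
#' @param model A `pet_model` (trained or not).
#' @param path Checkpoint file path (e.g. `model.rds`).
#' @return `save_model`: `path`, invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(kind = model$kind, spec = model$spec, classes = model$classes,
               init_seed = model$init_seed,
               config = if (!is.null(model$config)) unclass(model$config),
               stopped_epoch = model$stopped_epoch)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
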