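# Compact neural-network engine: 3D convolutions (im2col + BLAS GEMM), 2x2x2
# max pooling, dense heads, softmax cross-entropy, Adadelta, early stopping.
# Everything is seeded and single-threaded-deterministic.

#' Kernel-depth variants of the 3D model
#'
#' Four variants differing in convolution kernel depth: the first layer may
#' treat each axial slice separately (depth-1 kernel) and the remaining layers
#' use depth 3 or 6.
#'
#' @return Character vector of the four variant names.
#' @export
kernel_variants <- function() {
  c("first_3x3x1_rest_3x3x3", "all_3x3x3", "first_3x3x1_rest_3x3x6",
    "all_3x3x6")
}

kernel_shapes <- function(variant) {
  switch(variant,
    first_3x3x1_rest_3x3x3 = list(c(3, 3, 1), c(3, 3, 3), c(3, 3, 3), c(3, 3, 3)),
    all_3x3x3              = list(c(3, 3, 3), c(3, 3, 3), c(3, 3, 3), c(3, 3, 3)),
    first_3x3x1_rest_3x3x6 = list(c(3, 3, 1), c(3, 3, 6), c(3, 3, 6), c(3, 3, 6)),
    all_3x3x6              = list(c(3, 3, 6), c(3, 3, 6), c(3, 3, 6), c(3, 3, 6)),
    stop(sprintf("unknown kernel variant '%s'", variant), call. = FALSE)
  )
}

#' Architecture specification of the 3D model
#'
#' Four blocks of (3D convolution, ReLU, 2x2x2 max pool), a flatten, a dense
#' feature layer with ReLU, dropout, and a softmax output. `scale` multiplies
#' the convolution widths and the feature dimension for desk-scale runs.
#'
#' @param variant One of [kernel_variants()] (default homogeneous 3x3x3).
#' @param conv_widths Filter counts of the four convolution layers.
#' @param feature_dim Dense feature-layer width (the representation used for
#'   embeddings).
#' @param dropout Dropout rate on the feature layer, in `[0, 1)`.
#' @param n_classes 2, 3 or 4 output classes.
#' @param input_shape Expected input volume shape (after preprocessing).
#' @param scale Width multiplier (filters and feature_dim are rounded, min 1).
#' @return A list of class `pet_model_spec`.
#' @export
model_spec <- function(variant = "all_3x3x3",
                       conv_widths = c(32, 64, 128, 256),
                       feature_dim = 1024, dropout = 0.5, n_classes = 2,
                       input_shape = c(95, 79, 60), scale = 1) {
  variant <- match.arg(variant, kernel_variants())
  stopifnot(length(conv_widths) == 4, dropout >= 0, dropout < 1,
            n_classes >= 2, feature_dim > 0, scale > 0)
  structure(list(
    variant = variant,
    conv_widths = pmax(1L, as.integer(round(conv_widths * scale))),
    feature_dim = max(1L, as.integer(round(feature_dim * scale))),
    dropout = dropout, n_classes = as.integer(n_classes),
    input_shape = as.integer(input_shape), scale = scale
  ), class = "pet_model_spec")
}

#' Optimisation protocol
#'
#' Mini-batch training with the Adadelta optimiser and categorical
#' cross-entropy; optional early stopping monitors the validation loss and
#' halts after `patience` consecutive epochs with improvement below
#' `min_delta`, restoring the best-validation-loss weights.
#'
#' @param batch_size Mini-batch size (default 6).
#' @param learning_rate Adadelta learning-rate multiplier (default 0.01).
#' @param max_epochs Epoch budget (default 50; 100 for the fixed-epoch arm).
#' @param early_stopping Enable the stopping rule.
#' @param min_delta Minimum validation-loss improvement that counts
#'   (default 0.0001).
#' @param patience Consecutive non-improving epochs tolerated (default 10).
#' @param seed Seed for shuffling and dropout.
#' @param rho,epsilon Adadelta decay rate and numerical guard.
#' @return A list of class `pet_training_config`.
#' @export
training_config <- function(batch_size = 6L, learning_rate = 0.01,
                            max_epochs = 50L, early_stopping = TRUE,
                            min_delta = 1e-4, patience = 10L, seed = 1L,
                            rho = 0.95, epsilon = 1e-6) {
  stopifnot(batch_size >= 1, learning_rate > 0, max_epochs >= 1,
            min_delta >= 0, patience >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stopping = isTRUE(early_stopping),
                 min_delta = min_delta, patience = as.integer(patience),
                 seed = as.integer(seed), rho = rho, epsilon = epsilon),
            class = "pet_training_config")
}

# He-uniform init: variance 2/fan_in keeps ReLU activation scale stable
# through the conv stack (Glorot shrinks activations layer by layer here).
he_uniform <- function(nr, nc, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build the untrained 3D convolutional model
#'
#' @param spec A `pet_model_spec`.
#' @param seed Seed for the He-uniform weight initialisation.
#' @return An untrained model of class `pet_model` (kind `"cnn3d"`).
#' @export
build_3d_model <- function(spec = model_spec(), seed = 1L) {
  ks <- kernel_shapes(spec$variant)
  dims <- spec$input_shape
  shapes <- list()
  for (i in 1:4) {
    shapes[[i]] <- dims
    dims <- dims %/% 2L
    if (any(dims < 1))
      stop(sprintf(
        "input %s too small for 4 pooling stages (shape before stage %d: %s)",
        paste(spec$input_shape, collapse = "x"), i,
        paste(shapes[[i]], collapse = "x")), call. = FALSE)
  }
  widths <- spec$conv_widths
  cins <- c(1L, widths[1:3])
  params <- with_seed(seed, {
    conv <- purrr::map(1:4, function(i) {
      k <- ks[[i]]
      fan_k <- prod(k)
      W <- he_uniform(fan_k * cins[i], widths[i], fan_in = fan_k * cins[i])
      attr(W, "kshape") <- as.integer(k)
      attr(W, "cin") <- cins[i]
      list(W = W, b = numeric(widths[i]))
    })
    flat <- prod(dims) * widths[4]
    list(conv = conv,
         W1 = he_uniform(flat, spec$feature_dim, flat),
         b1 = numeric(spec$feature_dim),
         W2 = he_uniform(spec$feature_dim, spec$n_classes, spec$feature_dim),
         b2 = numeric(spec$n_classes))
  })
  structure(list(kind = "cnn3d", spec = spec, params = params,
                 classes = NULL, init_seed = as.integer(seed)),
            class = "pet_model")
}

build_mlp <- function(input_dim, hidden, n_classes, dropout, seed,
                      backbone_name = NULL) {
  params <- with_seed(seed, list(
    W1 = he_uniform(input_dim, hidden, input_dim),
    b1 = numeric(hidden),
    W2 = he_uniform(hidden, n_classes, hidden),
    b2 = numeric(n_classes)))
  spec <- list(feature_dim = as.integer(hidden), dropout = dropout,
               n_classes = as.integer(n_classes),
               input_dim = as.integer(input_dim))
  structure(list(kind = "mlp", spec = spec, params = params, classes = NULL,
                 backbone_name = backbone_name, init_seed = as.integer(seed)),
            class = "pet_model")
}

# ---- forward / backward ----------------------------------------------------

conv_forward_sample <- function(params, x, keep_cache = FALSE,
                                precol = NULL) {
  a <- array(as.numeric(x), dim = c(dim(x), 1L))
  caches <- if (keep_cache) vector("list", length(params$conv)) else NULL
  for (i in seq_along(params$conv)) {
    blk <- params$conv[[i]]
    k <- attr(blk$W, "kshape")
    in_dims <- dim(a)
    cols <- if (i == 1 && !is.null(precol)) precol
            else im2col3d(as.numeric(a), as.integer(in_dims), k[1], k[2], k[3])
    z <- cols %*% blk$W
    z <- sweep(z, 2, blk$b, `+`)
    mask <- z > 0
    z[!mask] <- 0
    zdims <- c(in_dims[1:3], ncol(blk$W))
    pooled <- maxpool3d_fwd(as.numeric(z), as.integer(zdims))
    if (keep_cache)
      caches[[i]] <- list(cols = cols, mask = mask, idx = pooled$idx,
                          in_dims = in_dims, zdims = zdims)
    a <- pooled$out
  }
  list(flat = as.numeric(a), out_dims = dim(a), caches = caches)
}

conv_backward_sample <- function(params, cache, dflat, grads) {
  d <- dflat
  for (i in rev(seq_along(params$conv))) {
    cc <- cache$caches[[i]]
    blk <- params$conv[[i]]
    d <- maxpool3d_bwd(as.numeric(d), cc$idx, as.integer(cc$zdims))
    dmat <- matrix(d, nrow = prod(cc$zdims[1:3]), ncol = cc$zdims[4])
    dmat[!cc$mask] <- 0
    grads$conv[[i]]$W <- grads$conv[[i]]$W + crossprod(cc$cols, dmat)
    grads$conv[[i]]$b <- grads$conv[[i]]$b + colSums(dmat)
    if (i > 1) {
      k <- attr(blk$W, "kshape")
      dcols <- dmat %*% t(blk$W)
      d <- col2im3d(dcols, as.integer(cc$in_dims), k[1], k[2], k[3])
    }
  }
  grads
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Dense head forward; `xs_mat` is the flattened conv output (cnn3d) or the
# input feature matrix (mlp).
head_forward <- function(params, xs_mat, dropout, training = FALSE) {
  z1 <- sweep(xs_mat %*% params$W1, 2, params$b1, `+`)
  a1 <- pmax(z1, 0)
  if (training && dropout > 0) {
    m <- matrix(runif(length(a1)) >= dropout, nrow(a1), ncol(a1))
    a1d <- a1 * m / (1 - dropout)
  } else {
    m <- NULL
    a1d <- a1
  }
  logits <- sweep(a1d %*% params$W2, 2, params$b2, `+`)
  list(z1 = z1, a1 = a1, a1d = a1d, mask = m, logits = logits,
       probs = softmax_rows(logits))
}

model_forward <- function(model, xs, training = FALSE, keep_cache = FALSE,
                          precols = NULL) {
  if (model$kind == "cnn3d") {
    conv <- lapply(seq_along(xs), function(i)
      conv_forward_sample(model$params, xs[[i]], keep_cache = keep_cache,
                          precol = precols[[i]]))
    mat <- do.call(rbind, lapply(conv, `[[`, "flat"))
  } else {
    conv <- NULL
    mat <- as.matrix(xs)
  }
  hd <- head_forward(model$params, mat, model$spec$dropout, training)
  c(hd, list(conv = conv, mat = mat))
}

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  z <- p * 0
  attributes(z) <- attributes(p)
  z
}

model_backward <- function(model, fwd, y_onehot) {
  n <- nrow(y_onehot)
  grads <- zero_like(model$params)
  dlogits <- (fwd$probs - y_onehot) / n
  grads$W2 <- crossprod(fwd$a1d, dlogits)
  grads$b2 <- colSums(dlogits)
  da1d <- dlogits %*% t(model$params$W2)
  da1 <- if (!is.null(fwd$mask)) da1d * fwd$mask / (1 - model$spec$dropout)
         else da1d
  dz1 <- da1 * (fwd$z1 > 0)
  grads$W1 <- crossprod(fwd$mat, dz1)
  grads$b1 <- colSums(dz1)
  if (model$kind == "cnn3d") {
    dmat <- dz1 %*% t(model$params$W1)
    for (i in seq_len(n))
      grads <- conv_backward_sample(model$params, fwd$conv[[i]], dmat[i, ],
                                    grads)
  }
  grads
}

# ---- Adadelta --------------------------------------------------------------

adadelta_step <- function(params, grads, state, cfg) {
  walk <- function(p, g, eg, ed) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, eg, ed), walk)
      return(list(p = lapply(out, `[[`, "p"), eg = lapply(out, `[[`, "eg"),
                  ed = lapply(out, `[[`, "ed")))
    }
    eg <- cfg$rho * eg + (1 - cfg$rho) * g^2
    delta <- -sqrt(ed + cfg$epsilon) / sqrt(eg + cfg$epsilon) * g
    ed <- cfg$rho * ed + (1 - cfg$rho) * delta^2
    pn <- p + cfg$learning_rate * delta
    attributes(pn) <- attributes(p)
    list(p = pn, eg = eg, ed = ed)
  }
  out <- walk(params, grads, state$eg, state$ed)
  list(params = out$p, state = list(eg = out$eg, ed = out$ed))
}

# ---- training --------------------------------------------------------------

as_class_factor <- function(y, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(y)))
  factor(as.character(y), levels = classes)
}

onehot <- function(yf) {
  k <- nlevels(yf)
  m <- matrix(0, length(yf), k)
  m[cbind(seq_along(yf), as.integer(yf))] <- 1
  m
}

subset_inputs <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
}

n_inputs <- function(x) if (is.matrix(x)) nrow(x) else length(x)

eval_model <- function(model, x, y_onehot, precols = NULL) {
  fwd <- model_forward(model, x, training = FALSE, precols = precols)
  p_true <- rowSums(fwd$probs * y_onehot)
  loss <- -mean(log(pmax(p_true, 1e-12)))
  acc <- mean(max.col(fwd$probs, ties.method = "first") ==
                max.col(y_onehot, ties.method = "first"))
  list(loss = loss, acc = acc)
}

#' Train a model
#'
#' Minimises categorical cross-entropy with Adadelta in mini-batches. With
#' early stopping on, training halts once the validation loss has failed to
#' improve by at least `min_delta` for `patience` consecutive epochs, and the
#' best-validation-loss weights are restored. Fully seeded: identical data,
#' config and seeds give identical weights.
#'
#' @param model An untrained `pet_model` from [build_3d_model()] or
#'   [build_tl_classifier()].
#' @param x Training inputs: a list of 3D arrays (`cnn3d`) or a feature matrix
#'   (`mlp`).
#' @param y Training labels (character or factor).
#' @param x_val,y_val Validation set, same forms; must be non-empty.
#' @param config A `pet_training_config`.
#' @return A `pet_trained_model`: the fitted model plus `history` (one row per
#'   epoch: train/val loss and accuracy) and `stopped_epoch`.
#' @export
train <- function(model, x, y, x_val, y_val, config = training_config()) {
  n <- n_inputs(x)
  if (n == 0 || n_inputs(x_val) == 0)
    stop("training and validation sets must be non-empty", call. = FALSE)
  classes <- model$classes %||%
    sort(unique(c(as.character(y), as.character(y_val))))
  if (length(classes) != model$spec$n_classes)
    stop(sprintf("model has %d output classes but data has %d labels",
                 model$spec$n_classes, length(classes)), call. = FALSE)
  yf <- as_class_factor(y, classes)
  yv <- as_class_factor(y_val, classes)
  Y <- onehot(yf)
  Yv <- onehot(yv)

  params <- model$params
  precols <- precols_val <- NULL
  if (model$kind == "cnn3d") {
    k1 <- attr(params$conv[[1]]$W, "kshape")
    bytes <- (n + n_inputs(x_val)) * prod(dim(x[[1]])) * prod(k1) * 8
    if (bytes < 1.5e9) {
      pre <- function(v) im2col3d(as.numeric(v),
                                  as.integer(c(dim(v), 1L)),
                                  k1[1], k1[2], k1[3])
      precols <- lapply(x, pre)
      precols_val <- lapply(x_val, pre)
    }
  }
  state <- list(eg = zero_like(params), ed = zero_like(params))
  history <- vector("list", config$max_epochs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  stopped <- config$max_epochs
  restored <- FALSE

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- subset_inputs(x, idx)
        yb <- Y[idx, , drop = FALSE]
        mwork <- model; mwork$params <- params
        fwd <- model_forward(mwork, xb, training = TRUE, keep_cache = TRUE,
                             precols = precols[idx])
        p_true <- rowSums(fwd$probs * yb)
        bl <- -mean(log(pmax(p_true, 1e-12)))
        if (!is.finite(bl))
          stop(sprintf("non-finite training loss at epoch %d", epoch),
               call. = FALSE)
        tot_loss <- tot_loss + bl * length(idx)
        tot_correct <- tot_correct +
          sum(max.col(fwd$probs, ties.method = "first") ==
                max.col(yb, ties.method = "first"))
        grads <- model_backward(mwork, fwd, yb)
        upd <- adadelta_step(params, grads, state, config)
        params <- upd$params
        state <- upd$state
      }
      mwork <- model; mwork$params <- params
      ev <- eval_model(mwork, x_val, Yv, precols = precols_val)
      if (!is.finite(ev$loss))
        stop(sprintf("non-finite validation loss at epoch %d", epoch),
             call. = FALSE)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = tot_loss / n, train_acc = tot_correct / n,
        val_loss = ev$loss, val_acc = ev$acc)
      if (best$loss - ev$loss > config$min_delta) {
        best <- list(loss = ev$loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (config$early_stopping && wait >= config$patience) {
          stopped <- epoch
          params <- best$params
          restored <- TRUE
          break
        }
      }
      stopped <- epoch
    }
  })

  model$params <- params
  model$classes <- classes
  model$history <- dplyr::bind_rows(history[!vapply(history, is.null,
                                                    logical(1))])
  model$stopped_epoch <- stopped
  model$best_epoch <- if (restored) best$epoch else stopped
  model$config <- config
  class(model) <- c("pet_trained_model", class(model))
  model
}

#' Class probabilities and labels
#'
#' Softmax probabilities (rows sum to 1) and argmax labels with lowest-index
#' tie-break.
#'
#' @param model A trained `pet_model` (or any object with a `predict_proba`
#'   method, e.g. [probe_model()]).
#' @param x Inputs (list of 3D arrays or feature matrix, matching the model).
#' @return `predict_proba`: numeric matrix (n x classes, named columns when
#'   class labels are known); `predict_labels`: character vector.
#' @export
predict_proba <- function(model, x) UseMethod("predict_proba")

#' @export
predict_proba.pet_model <- function(model, x) {
  fwd <- model_forward(model, x, training = FALSE)
  p <- fwd$probs
  if (!is.null(model$classes)) colnames(p) <- model$classes
  p
}

#' @rdname predict_proba
#' @export
predict_labels <- function(model, x) {
  p <- predict_proba(model, x)
  lab <- max.col(p, ties.method = "first")
  if (!is.null(colnames(p))) colnames(p)[lab] else as.character(lab)
}

#' Penultimate-layer features
#'
#' Activations of the dense feature layer (after ReLU, before dropout and the
#' classification layer), one row per input; 1024 columns for the full-size 3D
#' model.
#'
#' @param model A trained `pet_model`.
#' @param x Inputs matching the model kind.
#' @return Numeric matrix `n x feature_dim`.
#' @export
extract_features <- function(model, x) {
  fwd <- model_forward(model, x, training = FALSE)
  fwd$a1
}
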