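test_that("kernel-depth variants have exactly the specified kernel shapes", {
  expected <- list(
    first_3x3x1_rest_3x3x3 = list(c(3, 3, 1), c(3, 3, 3), c(3, 3, 3), c(3, 3, 3)),
    all_3x3x3              = list(c(3, 3, 3), c(3, 3, 3), c(3, 3, 3), c(3, 3, 3)),
    first_3x3x1_rest_3x3x6 = list(c(3, 3, 1), c(3, 3, 6), c(3, 3, 6), c(3, 3, 6)),
    all_3x3x6              = list(c(3, 3, 6), c(3, 3, 6), c(3, 3, 6), c(3, 3, 6)))
  expect_length(kernel_variants(), 4)
  for (v in kernel_variants()) {
    spec <- model_spec(variant = v, conv_widths = c(2, 2, 2, 2),
                       feature_dim = 4, n_classes = 2,
                       input_shape = c(16, 16, 16))
    m <- build_3d_model(spec, seed = 1)
    shapes <- lapply(m$params$conv, function(b) attr(b$W, "kshape"))
    expect_equal(shapes, lapply(expected[[v]], as.integer), ignore_attr = TRUE)
  }
})

test_that("the 3D model has 4 conv blocks and the declared head shape", {
  spec <- model_spec(conv_widths = c(3, 4, 5, 6), feature_dim = 7,
                     n_classes = 3, input_shape = c(16, 16, 16))
  m <- build_3d_model(spec, seed = 2)
  expect_length(m$params$conv, 4)
  expect_equal(vapply(m$params$conv, function(b) ncol(b$W), numeric(1)),
               c(3, 4, 5, 6))
  expect_equal(dim(m$params$W1), c(1 * 1 * 1 * 6, 7))
  expect_equal(dim(m$params$W2), c(7, 3))

  expect_error(build_3d_model(model_spec(input_shape = c(8, 16, 16))),
               "too small")
})

test_that("analytic gradients agree with central finite differences", {
  ns <- asNamespace("neuropet")
  spec <- model_spec(conv_widths = c(2, 3, 2, 2), feature_dim = 5,
                     n_classes = 2, input_shape = c(16, 16, 16), dropout = 0)
  m <- build_3d_model(spec, seed = 7)
  set.seed(3)
  xs <- list(array(runif(16^3), c(16, 16, 16)),
             array(runif(16^3), c(16, 16, 16)),
             array(runif(16^3), c(16, 16, 16)))
  Y <- rbind(c(1, 0), c(0, 1), c(1, 0))
  loss_fn <- function(params) {
    mm <- m; mm$params <- params
    fwd <- ns$model_forward(mm, xs, training = FALSE)
    -mean(log(pmax(rowSums(fwd$probs * Y), 1e-12)))
  }
  fwd <- ns$model_forward(m, xs, training = TRUE, keep_cache = TRUE)
  g <- ns$model_backward(m, fwd, Y)
  eps <- 1e-5
  check <- function(get, set, label) {
    vals <- get(m$params)
    set.seed(42 + nchar(label))
    for (i in sample(length(vals), min(4, length(vals)))) {
      up <- m$params; dn <- m$params
      vu <- get(up); vu[i] <- vu[i] + eps
      vd <- get(dn); vd[i] <- vd[i] - eps
      num <- (loss_fn(set(up, vu)) - loss_fn(set(dn, vd))) / (2 * eps)
      expect_equal(get(g)[i], num, tolerance = 1e-4,
                   label = sprintf("%s[%d] analytic", label, i))
    }
  }
  keep_attrs <- function(p, v, tmpl) { attributes(v) <- attributes(tmpl); v }
  check(function(p) p$conv[[1]]$W,
        function(p, v) { p$conv[[1]]$W <- keep_attrs(p, v, p$conv[[1]]$W); p },
        "conv1.W")
  check(function(p) p$conv[[3]]$W,
        function(p, v) { p$conv[[3]]$W <- keep_attrs(p, v, p$conv[[3]]$W); p },
        "conv3.W")
  check(function(p) p$conv[[2]]$b,
        function(p, v) { p$conv[[2]]$b <- v; p }, "conv2.b")
  check(function(p) p$W1, function(p, v) { dim(v) <- dim(p$W1); p$W1 <- v; p },
        "W1")
  check(function(p) p$W2, function(p, v) { dim(v) <- dim(p$W2); p$W2 <- v; p },
        "W2")
})

test_that("softmax predictions are proper probabilities with stable argmax", {
  bb <- standin_backbone(seed = 1, feature_dim = 16)
  head <- build_tl_classifier(bb, n_classes = 3, head_hidden = 8, seed = 1)
  set.seed(4)
  x <- matrix(rnorm(5 * 16), 5, 16)
  y <- c("a", "b", "c", "a", "b")
  fit <- train(head, x, y, x, y,
               training_config(max_epochs = 2, batch_size = 2, seed = 1))
  p <- predict_proba(fit, x)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0))
  lab <- predict_labels(fit, x)
  expect_equal(lab, colnames(p)[max.col(p, ties.method = "first")])

  # exact tie -> lowest-index class
  tie <- fit
  tie$params$W1[] <- 0; tie$params$b1[] <- 0
  tie$params$W2[] <- 0; tie$params$b2[] <- 0
  expect_true(all(predict_labels(tie, x) == "a"))
})

test_that("stand-in backbone is frozen, seeded, and input-sensitive", {
  m1 <- matrix(runif(60 * 50), 60, 50)
  bb <- standin_backbone(seed = 5, feature_dim = 32)
  f1 <- backbone_features(bb, m1)
  expect_equal(dim(f1), c(1, 32))
  expect_identical(f1, backbone_features(bb, m1))
  expect_false(isTRUE(all.equal(
    f1, backbone_features(standin_backbone(seed = 6, feature_dim = 32), m1))))

  # perturbing one tile of the mosaic changes the features
  m2 <- m1
  m2[1:10, 1:10] <- m2[1:10, 1:10] + 0.5
  expect_false(isTRUE(all.equal(f1, backbone_features(bb, m2))))

  # 3-channel replicated input gives the same features as the grey image
  expect_equal(backbone_features(bb, replicate_rgb(m1)), f1,
               ignore_attr = TRUE)
})

test_that("backbone outputs are bit-identical before and after head training", {
  bb <- standin_backbone(seed = 2, feature_dim = 16)
  mos <- lapply(1:8, function(i) matrix(runif(40 * 30), 40, 30))
  before <- backbone_features(bb, mos)
  head <- build_tl_classifier(bb, n_classes = 2, head_hidden = 8, seed = 1)
  y <- rep(c("x", "y"), 4)
  fit <- train(head, before, y, before, y,
               training_config(max_epochs = 3, batch_size = 4, seed = 1))
  after <- backbone_features(bb, mos)
  expect_identical(before, after)
  # identical features -> identical head logits
  expect_identical(predict_proba(fit, before), predict_proba(fit, after))
})

test_that("extract_features returns one penultimate row per input", {
  bb <- standin_backbone(seed = 3, feature_dim = 12)
  head <- build_tl_classifier(bb, n_classes = 2, head_hidden = 6, seed = 1)
  x <- matrix(rnorm(8 * 12), 8, 12)
  y <- rep(c("p", "q"), 4)
  fit <- train(head, x, y, x, y, training_config(max_epochs = 2,
                                                 batch_size = 4, seed = 1))
  f <- extract_features(fit, x)
  expect_equal(dim(f), c(8, 6))
  expect_identical(f[1, ], extract_features(fit, x[c(1, 1), ])[2, ])
})

test_that("model checkpoints round-trip with a JSON sidecar", {
  bb <- standin_backbone(seed = 4, feature_dim = 8)
  head <- build_tl_classifier(bb, n_classes = 2, head_hidden = 4, seed = 2)
  x <- matrix(rnorm(6 * 8), 6, 8); y <- rep(c("u", "v"), 3)
  fit <- train(head, x, y, x, y, training_config(max_epochs = 2, seed = 1))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(predict_proba(back, x), predict_proba(fit, x))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$kind, "mlp")
  expect_equal(unlist(meta$classes), c("u", "v"))
})
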