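test_that("stratified splits partition each stratum to within one case", {
  m <- generate_cohort(scaled_config(seed = 5), generate_volumes = FALSE)$manifest
  out <- stratified_split(m, test_fraction = 0.2, val_fraction = 0.25,
                          seed = 3)
  expect_setequal(unique(out$split), c("train", "val", "test"))
  expect_equal(nrow(out), nrow(m))
  key <- paste(out$class, out$site)
  for (k in unique(key)) {
    i <- key == k
    n <- sum(i)
    expect_lte(abs(sum(out$split[i] == "test") - 0.2 * n), 1)
  }
  # deterministic under seed
  expect_identical(out, stratified_split(m, 0.2, 0.25, seed = 3))
  expect_error(stratified_split(m, test_fraction = 0), "test_fraction")
})

test_that("external rows are untouched and small strata fall back to train", {
  m <- generate_cohort(scaled_config(seed = 5), generate_volumes = FALSE)$manifest
  ext <- generate_external_ftld(scaled_config(seed = 5),
                                generate_volumes = FALSE)$manifest
  all <- dplyr::bind_rows(m, ext)
  out <- stratified_split(all, 0.2, 0.25, seed = 1)
  expect_true(all(out$split[out$class == "FTLD"] == "external"))

  tiny <- tibble::tibble(subject_id = c("a", "b"),
                         class = c("AD", "CN"), site = "A",
                         age = 70, sex = "F", split = "train")
  expect_warning(out2 <- stratified_split(tiny, 0.2, 0.2, seed = 1),
                 "fewer than 2")
  expect_true(all(out2$split == "train"))
})

test_that("k-fold CV builds exact stratified partitions", {
  set.seed(1)
  y <- rep(c("a", "b"), each = 5)
  x <- matrix(rnorm(10 * 2), 10, 2)
  majority_learner <- function(x_tr, y_tr, x_val, y_val, seed = 1) {
    lev <- names(sort(table(y_tr), decreasing = TRUE))[1]
    structure(list(lev = lev), class = "majority_clf")
  }
  # a predict_proba method for the stub, registered for S3 dispatch
  assign("predict_proba.majority_clf",
         function(model, x) {
           p <- matrix(0, nrow(x), 2, dimnames = list(NULL, c("a", "b")))
           p[, model$lev] <- 1
           p
         }, envir = globalenv())
  withr::defer(rm("predict_proba.majority_clf", envir = globalenv()))

  cv <- kfold_cv(x, y, majority_learner, k_values = 2, rounds = 3, seed = 7)
  expect_equal(nrow(cv$folds), 2 * 3)
  # folds of size 5, 5 and every item validated exactly once per round:
  # with balanced classes the majority learner's val accuracy is the majority
  # fraction 0.5 up to the tie-break
  expect_true(all(cv$folds$val_acc %in% c(0, 0.4, 0.5, 0.6, 1)))
  expect_true(all(cv$summary$val_ci >= 0))
  expect_error(kfold_cv(x, y, majority_learner, k_values = 11, rounds = 1),
               "exceeds")
})

test_that("fold membership is a partition for every round", {
  ns <- asNamespace("neuropet")
  y <- rep(c("a", "b", "c"), times = c(7, 6, 5))
  for (k in c(2, 3, 6)) {
    set.seed(k)
    fold <- ns$stratified_folds(y, k)
    expect_setequal(unique(fold), seq_len(k))
    # stratification error <= 1 per class per fold
    for (cls in unique(y)) {
      tab <- tabulate(fold[y == cls], k)
      expect_lte(max(tab) - min(tab), 1)
    }
  }
})

test_that("the 95% CI uses the Student-t closed form", {
  expect_equal(confidence_interval_95(rep(0.7, 6))$half_width, 0)
  ci <- confidence_interval_95(c(0, 1))
  expect_equal(ci$mean, 0.5)
  expect_equal(ci$half_width, qt(0.975, 1) * sd(c(0, 1)) / sqrt(2))
  expect_error(confidence_interval_95(0.3), "at least 2")

  # agreement with a bootstrap percentile CI on a normal sample
  set.seed(2)
  v <- rnorm(100, 10, 2)
  ci2 <- confidence_interval_95(v)
  boots <- replicate(2000, mean(sample(v, replace = TRUE)))
  half_boot <- diff(unname(quantile(boots, c(0.025, 0.975)))) / 2
  expect_lt(abs(ci2$half_width - half_boot) / half_boot, 0.1)
})

test_that("NMI matches its definition, symmetry and relabel invariance", {
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(nmi(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_error(nmi(1:4, 1:3), "length")

  set.seed(3)
  for (i in 1:25) {
    a <- sample(0:2, 12, TRUE)
    b <- sample(0:3, 12, TRUE)
    expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
    expect_equal(nmi(a, b), nmi_oracle(a, b), tolerance = 1e-10)
    expect_gte(nmi(a, b), 0)
    expect_lte(nmi(a, b), 1)
  }
})

test_that("one-vs-rest ROC analysis matches the pair-counting oracle", {
  set.seed(4)
  y <- sample(c("a", "b", "c"), 30, TRUE)
  p <- matrix(runif(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  p <- p / rowSums(p)
  roc <- roc_analysis(p, y)
  for (cls in c("a", "b", "c")) {
    expect_equal(roc$auc$auc[roc$auc$class == cls],
                 auc_oracle(p[, cls], as.integer(y == cls)),
                 tolerance = 1e-10)
  }
  expect_equal(roc$macro_auc, mean(roc$auc$auc))

  # perfectly separating scores
  y2 <- rep(c("a", "b"), each = 5)
  p2 <- cbind(a = c(rep(0.9, 5), rep(0.1, 5)),
              b = c(rep(0.1, 5), rep(0.9, 5)))
  roc2 <- roc_analysis(p2, y2)
  expect_equal(roc2$auc$auc, c(1, 1))
  expect_equal(roc2$macro_auc, 1)

  # absent class: warned, excluded from the macro average
  y3 <- rep(c("a", "b"), each = 5)
  p3 <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(roc3 <- roc_analysis(p3, y3), "absent")
  expect_true(is.na(roc3$auc$auc[roc3$auc$class == "c"]))
  expect_equal(roc3$macro_auc,
               mean(roc3$auc$auc[roc3$auc$class != "c"]))
})

test_that("label-independent scores give chance AUC", {
  set.seed(5)
  y <- sample(c("a", "b"), 400, TRUE)
  p <- matrix(runif(800), 400, 2, dimnames = list(NULL, c("a", "b")))
  p <- p / rowSums(p)
  roc <- roc_analysis(p, y)
  expect_lt(abs(roc$macro_auc - 0.5), 0.08)
})

test_that("2D embedding separates well-separated clusters", {
  set.seed(6)
  f <- rbind(matrix(rnorm(15 * 5, 0), 15, 5),
             matrix(rnorm(15 * 5, 8), 15, 5))
  emb <- embed_2d(f, seed = 2)
  expect_equal(dim(emb), c(30, 2), ignore_attr = TRUE)
  expect_identical(emb, embed_2d(f, seed = 2))
  km <- kmeans(as.matrix(emb), centers = 2, nstart = 5)
  expect_gt(silhouette_mean(as.matrix(emb), km$cluster), 0.5)
  expect_error(embed_2d(f[1:5, ]), ">= 10")
})
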