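# Splits, repeated stratified k-fold CV, confidence intervals, NMI,
# one-vs-rest ROC/AUC and 2D feature embedding.

#' Stratified train/validation/test split
#'
#' Assigns each non-external manifest row to train, val or test, stratifying
#' by (class, site) so both disorders and acquisition sources stay
#' represented: per stratum, `round(test_fraction * n)` cases go to test and
#' `round(val_fraction * n_remaining)` of the rest to val. External rows are
#' never touched. Strata smaller than 2 are assigned wholly to train with a
#' warning.
#'
#' @param manifest Cohort manifest tibble (columns `class`, `site`, `split`).
#' @param test_fraction Outer test fraction in `(0, 1)`; 0.11 mirrors the main
#'   89/11 split, 0.10 the split used for the 4-way ROC analysis.
#' @param val_fraction Validation fraction within the remaining training part.
#' @param seed RNG seed.
#' @return The manifest with its `split` column filled in.
#' @export
stratified_split <- function(manifest, test_fraction = 0.11,
                             val_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            val_fraction >= 0, val_fraction < 1)
  ext <- manifest$split == "external"
  work <- manifest[!ext, ]
  assign_stratum <- function(n) {
    spl <- rep("train", n)
    if (n < 2) return(spl)
    n_test <- round(test_fraction * n)
    n_val <- round(val_fraction * (n - n_test))
    ord <- sample.int(n)
    if (n_test > 0) spl[ord[seq_len(n_test)]] <- "test"
    if (n_val > 0) spl[ord[n_test + seq_len(n_val)]] <- "val"
    spl
  }
  with_seed(seed, {
    key <- paste(work$class, work$site)
    small <- names(which(table(key) < 2))
    if (length(small) > 0)
      warning(sprintf("stratum(s) %s have fewer than 2 cases; assigned to train",
                      paste(small, collapse = ", ")), call. = FALSE)
    new_split <- character(nrow(work))
    for (k in unique(key)) {
      i <- which(key == k)
      new_split[i] <- assign_stratum(length(i))
    }
    work$split <- new_split
  })
  manifest$split[!ext] <- work$split
  manifest
}

stratified_folds <- function(y, k) {
  if (k > length(y)) stop(sprintf("k = %d exceeds n = %d", k, length(y)),
                          call. = FALSE)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    i <- i[sample.int(length(i))]
    fold[i] <- rep(seq_len(k), length.out = length(i))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' For each `k` and each round, the data are reshuffled into stratified k
#' folds and the model is retrained from scratch on each fold's complement,
#' with the held-out fold as validation set. 95% confidence intervals are
#' computed over all fold-by-round values.
#'
#' @param x Inputs (list of volumes or a feature matrix).
#' @param y Labels.
#' @param learner Function `(x_tr, y_tr, x_val, y_val, seed)` returning a
#'   trained model (see [cnn_learner()]), or any object with
#'   [predict_labels()] support.
#' @param k_values Fold counts to sweep (default 2:10).
#' @param rounds Independent reshuffled repetitions per k (default 10).
#' @param seed Master seed; each (k, round, fold) gets a derived seed.
#' @return A list of class `pet_cv`: `folds` (tibble with one row per
#'   k/round/fold: train_acc, val_acc) and `summary` (per-k mean and 95% CI
#'   half-width of both accuracies).
#' @export
kfold_cv <- function(x, y, learner, k_values = 2:10, rounds = 10, seed = 1L) {
  stopifnot(all(k_values >= 2))
  y <- as.character(y)
  rows <- list()
  for (k in k_values) {
    for (r in seq_len(rounds)) {
      fold <- with_seed(seed + 1000L * k + r, stratified_folds(y, k))
      for (f in seq_len(k)) {
        tr <- which(fold != f)
        va <- which(fold == f)
        fit <- learner(subset_inputs(x, tr), y[tr],
                       subset_inputs(x, va), y[va],
                       seed = seed + 1000L * k + 10L * r + f)
        rows[[length(rows) + 1]] <- tibble::tibble(
          k = k, round = r, fold = f,
          train_acc = mean(predict_labels(fit, subset_inputs(x, tr)) == y[tr]),
          val_acc = mean(predict_labels(fit, subset_inputs(x, va)) == y[va]))
      }
    }
  }
  folds <- dplyr::bind_rows(rows)
  summary <- folds |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(
      train_acc = mean(.data$train_acc),
      train_ci = ci95_half_width(.data$train_acc),
      val_acc_mean = mean(.data$val_acc),
      val_ci = ci95_half_width(.data$val_acc), .groups = "drop") |>
    dplyr::rename(val_acc = "val_acc_mean")
  structure(list(folds = folds, summary = summary), class = "pet_cv")
}

ci95_half_width <- function(values) {
  n <- length(values)
  if (n < 2) return(0)
  qt(0.975, n - 1) * sd(values) / sqrt(n)
}

#' Student-t 95% confidence interval
#'
#' Mean plus/minus `t(0.975, n-1) * sd / sqrt(n)`.
#'
#' @param values Numeric vector with at least 2 values.
#' @return Tibble with columns `mean`, `half_width`, `n`.
#' @export
confidence_interval_95 <- function(values) {
  if (length(values) < 2)
    stop("need at least 2 values for a confidence interval", call. = FALSE)
  tibble::tibble(mean = mean(values),
                 half_width = ci95_half_width(values),
                 n = length(values))
}

#' Normalised mutual information between two labelings
#'
#' Mutual information of the joint contingency table normalised by the
#' arithmetic mean of the two marginal entropies (natural log). Equals 1 iff
#' the two partitions are identical up to relabeling, 0 under independence.
#' When both labelings are single-cluster the partitions are identical and the
#' value is defined as 1; when exactly one is single-cluster, as 0.
#'
#' @param y_true,y_pred Equal-length non-empty label vectors.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(y_true), length(y_pred)), call. = FALSE)
  if (length(y_true) == 0) stop("empty label vectors", call. = FALSE)
  tab <- table(y_true, y_pred)
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h1 <- h(pj); h2 <- h(pk)
  p <- tab / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (pj[row(p)[nz]] * pk[col(p)[nz]])))
  if (h1 == 0 && h2 == 0) return(1)
  if (h1 == 0 || h2 == 0) return(0)
  min(1, max(0, mi / ((h1 + h2) / 2)))
}

#' One-vs-rest ROC analysis
#'
#' Per-class ROC curves and trapezoidal AUC (via pROC), plus the macro-average
#' AUC (unweighted mean over classes). A class absent from `y_true` gets an
#' undefined AUC and is excluded from the macro average with a warning.
#'
#' @param probabilities Numeric matrix, one column per class (named), rows
#'   summing to 1.
#' @param y_true True labels (values among the column names).
#' @return A list of class `pet_roc`: `auc` (tibble class/auc), `macro_auc`,
#'   `roc_points` (tibble class/fpr/tpr).
#' @export
roc_analysis <- function(probabilities, y_true) {
  classes <- colnames(probabilities)
  if (is.null(classes)) stop("probability matrix must have named columns",
                             call. = FALSE)
  y_true <- as.character(y_true)
  if (length(unique(y_true)) < 2)
    stop("need at least 2 classes present in y_true", call. = FALSE)
  aucs <- numeric(0)
  pts <- list()
  auc_tab <- purrr::map_dfr(classes, function(cls) {
    if (!cls %in% y_true) {
      warning(sprintf("class '%s' absent from y_true; AUC undefined", cls),
              call. = FALSE)
      return(tibble::tibble(class = cls, auc = NA_real_))
    }
    resp <- factor(ifelse(y_true == cls, "pos", "neg"),
                   levels = c("neg", "pos"))
    r <- pROC::roc(response = resp, predictor = probabilities[, cls],
                   levels = c("neg", "pos"), direction = "<", quiet = TRUE)
    pts[[cls]] <<- tibble::tibble(class = cls,
                                  fpr = rev(1 - r$specificities),
                                  tpr = rev(r$sensitivities))
    tibble::tibble(class = cls, auc = as.numeric(pROC::auc(r)))
  })
  structure(list(auc = auc_tab,
                 macro_auc = mean(auc_tab$auc, na.rm = TRUE),
                 roc_points = dplyr::bind_rows(pts)),
            class = "pet_roc")
}

#' Unsupervised 2D embedding of feature representations
#'
#' Nonmetric multidimensional scaling (isoMDS, classical-MDS initialisation)
#' of the Euclidean feature distances: an unsupervised nonlinear projection to
#' 2D that preserves neighbourhood structure. No labels are used. The
#' procedure is deterministic for a given seed.
#'
#' @param features Numeric matrix with at least 10 rows.
#' @param seed RNG seed (used only to jitter exactly duplicated rows, which
#'   nonmetric scaling cannot host at zero distance).
#' @return Tibble with columns `dim1`, `dim2` (one row per feature row).
#' @export
embed_2d <- function(features, seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) < 10)
    stop(sprintf("need >= 10 rows to embed, got %d", nrow(features)),
         call. = FALSE)
  d <- dist(features)
  eps <- max(1e-8, stats::median(d) * 1e-6)
  if (any(d < eps)) {
    jit <- with_seed(seed, matrix(rnorm(length(features), 0, eps),
                                  nrow(features)))
    d <- dist(features + jit)
    d[d < eps] <- eps
  }
  init <- cmdscale(d, k = 2)
  if (ncol(init) < 2)
    init <- cbind(init, with_seed(seed + 1L, rnorm(nrow(features), 0, eps)))
  fit <- MASS::isoMDS(d, y = init, k = 2, trace = FALSE)
  tibble::tibble(dim1 = fit$points[, 1], dim2 = fit$points[, 2])
}

#' Evaluate one classification task end to end
#'
#' Trains with the given learner on the train split, evaluates on the val
#' split, and reports accuracy, NMI between true and predicted labels, and
#' (optionally) the ROC analysis.
#'
#' @param x,y Inputs and labels.
#' @param split Character vector aligned with `x` with values
#'   `train`/`val`/`test`.
#' @param learner Learner function (see [cnn_learner()]).
#' @param seed Seed forwarded to the learner.
#' @param roc Also compute the one-vs-rest ROC on the val split.
#' @return A list: `model`, tibble `metrics` (train_acc, val_acc, nmi), and
#'   `roc` when requested.
#' @export
evaluate_task <- function(x, y, split, learner, seed = 1L, roc = FALSE) {
  tr <- which(split == "train")
  va <- which(split == "val")
  fit <- learner(subset_inputs(x, tr), y[tr], subset_inputs(x, va), y[va],
                 seed = seed)
  pred_tr <- predict_labels(fit, subset_inputs(x, tr))
  pred_va <- predict_labels(fit, subset_inputs(x, va))
  metrics <- tibble::tibble(
    train_acc = mean(pred_tr == y[tr]),
    val_acc = mean(pred_va == y[va]),
    nmi = nmi(y[va], pred_va))
  out <- list(model = fit, metrics = metrics)
  if (roc) out$roc <- roc_analysis(predict_proba(fit, subset_inputs(x, va)),
                                   y[va])
  out
}
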