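# End-to-end experiment orchestration: simulate -> preprocess -> train ->
# evaluate (-> occlusion / robustness), with seeded, checksummed reports.

#' Plan one of the study's experiments
#'
#' Experiment ids mirror the comparative-analysis design: kernel-variant
#' selection by repeated k-fold CV, early-stopping vs fixed-epoch training,
#' the learning-rate x dropout grid, the binary/3-way/4-way model comparison,
#' the 4-way ROC/embedding analysis, and the external-case robustness probe.
#' Defaults run everything at desk scale (see [scaled_config()]).
#'
#' @param experiment One of `kernel_variants`, `stopping_strategy`,
#'   `lr_dropout_grid`, `multitask_compare`, `fourway_analysis`, `robustness`.
#' @param task `binary` (AD vs CN), `3way` (+DLB) or `4way` (+MCI).
#' @param sim_config,prep_config Simulation and preprocessing configurations.
#' @param model_scale Width multiplier of the 3D model.
#' @param dropout Feature-layer dropout used by the planned models (desk-scale
#'   default 0; the lr_dropout_grid experiment sweeps its own grid).
#' @param training A `pet_training_config`.
#' @param seeds Integer vector of replicate seeds.
#' @param k_values,rounds CV sweep (kernel_variants).
#' @param lr_grid,dropout_grid Hyperparameter grids (lr_dropout_grid).
#' @param models Character subset of `c("cnn3d", "tl")`.
#' @return A list of class `pet_experiment_plan`.
#' @export
experiment_plan <- function(experiment = c("kernel_variants",
                                           "stopping_strategy",
                                           "lr_dropout_grid",
                                           "multitask_compare",
                                           "fourway_analysis", "robustness"),
                            task = "4way",
                            sim_config = scaled_config(),
                            prep_config = scaled_preprocess_config(),
                            model_scale = 0.125,
                            dropout = 0,
                            training = training_config(learning_rate = 0.3,
                                                       max_epochs = 32,
                                                       patience = 16),
                            seeds = 1L,
                            k_values = c(2L, 5L), rounds = 2L,
                            lr_grid = c(0.1, 0.01, 0.001),
                            dropout_grid = c(0.2, 0.3, 0.4, 0.5),
                            models = c("cnn3d", "tl")) {
  experiment <- match.arg(experiment)
  stopifnot(length(lr_grid) > 0, length(dropout_grid) > 0)
  structure(list(experiment = experiment, task = task,
                 sim_config = sim_config, prep_config = prep_config,
                 model_scale = model_scale, dropout = dropout,
                 training = training,
                 seeds = as.integer(seeds), k_values = as.integer(k_values),
                 rounds = as.integer(rounds), lr_grid = lr_grid,
                 dropout_grid = dropout_grid, models = models),
            class = "pet_experiment_plan")
}

task_classes <- function(task) {
  switch(task,
         binary = c("AD", "CN"),
         `3way` = c("AD", "CN", "DLB"),
         `4way` = c("AD", "CN", "DLB", "MCI"),
         stop(sprintf("unknown task '%s'", task), call. = FALSE))
}

trimmed_shape <- function(sim_config, prep_config) {
  s <- sim_config$raw_shape
  c(s[1], s[2], s[3] - prep_config$drop_head - prep_config$drop_tail)
}

plan_model_spec <- function(plan, n_classes) {
  model_spec(scale = plan$model_scale, n_classes = n_classes,
             dropout = plan$dropout,
             input_shape = trimmed_shape(plan$sim_config, plan$prep_config))
}

# simulate + preprocess, cached in the workspace so downstream experiment
# stages can be rerun without regenerating the cohort.
pipeline_cohort <- function(plan, workspace) {
  key <- rlang::hash(list(plan$sim_config, plan$prep_config))
  cache <- file.path(workspace, sprintf("cohort_%s.rds", substr(key, 1, 12)))
  if (file.exists(cache)) return(readRDS(cache))
  coh <- generate_cohort(plan$sim_config)
  coh <- preprocess_cohort(coh, plan$prep_config)
  coh$manifest <- stratified_split(coh$manifest, test_fraction = 0.11,
                                   val_fraction = 0.2,
                                   seed = plan$sim_config$seed)
  saveRDS(coh, cache)
  coh
}

task_data <- function(cohort, task) {
  keep <- cohort$manifest$class %in% task_classes(task)
  list(x = cohort$volumes[keep],
       y = cohort$manifest$class[keep],
       split = cohort$manifest$split[keep],
       manifest = cohort$manifest[keep, ])
}

run_multitask <- function(plan, cohort) {
  backbone <- standin_backbone(seed = 1L)
  purrr::map_dfr(c("binary", "3way", "4way"), function(task) {
    td <- task_data(cohort, task)
    use <- td$split %in% c("train", "val")
    purrr::map_dfr(plan$models, function(mdl) {
      purrr::map_dfr(plan$seeds, function(s) {
        if (mdl == "cnn3d") {
          x <- td$x[use]
          learner <- cnn_learner(plan_model_spec(plan,
                                                 length(task_classes(task))),
                                 plan$training)
        } else {
          mos <- lapply(td$x[use], volume_to_mosaic, config = plan$prep_config)
          x <- backbone_features(backbone, mos)
          learner <- cnn_learner(NULL, plan$training, backbone = backbone)
        }
        t0 <- proc.time()[["elapsed"]]
        res <- evaluate_task(x, td$y[use], td$split[use], learner, seed = s)
        dplyr::mutate(res$metrics, task = task, model = mdl, seed = s,
                      wall_time = proc.time()[["elapsed"]] - t0,
                      .before = 1)
      })
    })
  })
}

run_kernel_variants <- function(plan, cohort) {
  td <- task_data(cohort, plan$task)
  use <- td$split %in% c("train", "val")
  purrr::map_dfr(kernel_variants(), function(v) {
    sp <- plan_model_spec(plan, length(task_classes(plan$task)))
    sp$variant <- v
    cv <- kfold_cv(td$x[use], td$y[use], cnn_learner(sp, plan$training),
                   k_values = plan$k_values, rounds = plan$rounds,
                   seed = plan$seeds[1])
    dplyr::mutate(cv$summary, variant = v, .before = 1)
  })
}

run_stopping_strategy <- function(plan, cohort) {
  td <- task_data(cohort, plan$task)
  tr <- which(td$split == "train"); va <- which(td$split == "val")
  purrr::map_dfr(c(TRUE, FALSE), function(es) {
    cfg <- plan$training
    cfg$early_stopping <- es
    if (!es) cfg$max_epochs <- max(cfg$max_epochs, 2L * cfg$max_epochs)
    fit <- train(build_3d_model(plan_model_spec(plan,
                                                length(task_classes(plan$task))),
                                seed = plan$seeds[1]),
                 td$x[tr], td$y[tr], td$x[va], td$y[va], cfg)
    dplyr::mutate(glance(fit), early_stopping = es, .before = 1)
  })
}

run_lr_dropout_grid <- function(plan, cohort) {
  td <- task_data(cohort, plan$task)
  tr <- which(td$split == "train"); va <- which(td$split == "val")
  grid <- tidyr::expand_grid(lr = plan$lr_grid, dropout = plan$dropout_grid)
  purrr::pmap_dfr(grid, function(lr, dropout) {
    sp <- plan_model_spec(plan, length(task_classes(plan$task)))
    sp$dropout <- dropout
    cfg <- plan$training
    cfg$learning_rate <- lr
    fit <- train(build_3d_model(sp, seed = plan$seeds[1]),
                 td$x[tr], td$y[tr], td$x[va], td$y[va], cfg)
    dplyr::mutate(glance(fit), lr = lr, dropout = dropout, .before = 1)
  })
}

run_fourway_analysis <- function(plan, cohort) {
  td <- task_data(cohort, "4way")
  man <- stratified_split(td$manifest, test_fraction = 0.10,
                          val_fraction = 0.2, seed = plan$seeds[1])
  tr <- which(man$split %in% c("train", "val"))
  te <- which(man$split == "test")
  fit <- train(build_3d_model(plan_model_spec(plan, 4), seed = plan$seeds[1]),
               td$x[man$split == "train"], td$y[man$split == "train"],
               td$x[man$split == "val"], td$y[man$split == "val"],
               plan$training)
  roc <- roc_analysis(predict_proba(fit, td$x[te]), td$y[te])
  feats <- extract_features(fit, td$x[tr])
  emb <- embed_2d(feats, seed = plan$seeds[1])
  emb$class <- td$y[tr]
  list(model = fit, roc = roc, embedding = emb,
       test_acc = mean(predict_labels(fit, td$x[te]) == td$y[te]))
}

run_robustness <- function(plan, cohort) {
  td <- task_data(cohort, "4way")
  tr <- which(td$split == "train"); va <- which(td$split == "val")
  fit <- train(build_3d_model(plan_model_spec(plan, 4), seed = plan$seeds[1]),
               td$x[tr], td$y[tr], td$x[va], td$y[va], plan$training)
  ext <- generate_external_ftld(plan$sim_config)
  ext <- preprocess_cohort(ext, plan$prep_config)
  rob <- predict_external(fit, ext$volumes)
  emb <- joint_embedding(extract_features(fit, td$x[tr]),
                         extract_features(fit, ext$volumes),
                         seed = plan$seeds[1])
  list(report = rob, embedding = emb,
       cohesion = if (length(ext$volumes) >= 2)
         cohesion_statistic(emb[, c("dim1", "dim2")], emb$external) else NA)
}

#' Run one planned experiment end to end
#'
#' Executes simulate, preprocess, train, evaluate (and occlusion/robustness
#' stages where the experiment requires them), writes the result tables to the
#' workspace, and returns a run record with seeds, the plan hash and output
#' checksums. Reruns with the same plan and seed reproduce the same numbers;
#' the simulated cohort is cached in the workspace and reused.
#'
#' @param plan A `pet_experiment_plan`.
#' @param workspace Writable directory for caches and reports.
#' @return A list of class `pet_run_record`: `experiment`, `timestamp`,
#'   `config_hash`, `seed`, `outputs` (tibble path/md5), `result`.
#' @export
run_experiment <- function(plan, workspace) {
  if (!dir.exists(workspace))
    dir.create(workspace, recursive = TRUE)
  cohort <- pipeline_cohort(plan, workspace)
  result <- switch(plan$experiment,
    multitask_compare = run_multitask(plan, cohort),
    kernel_variants = run_kernel_variants(plan, cohort),
    stopping_strategy = run_stopping_strategy(plan, cohort),
    lr_dropout_grid = run_lr_dropout_grid(plan, cohort),
    fourway_analysis = run_fourway_analysis(plan, cohort),
    robustness = run_robustness(plan, cohort))
  files <- character(0)
  base <- file.path(workspace, plan$experiment)
  if (is.data.frame(result)) {
    f <- paste0(base, ".csv")
    # wall time is hardware-dependent and excluded so that reruns with the
    # same plan and seed write byte-identical reports
    utils::write.csv(result[setdiff(names(result), "wall_time")], f,
                     row.names = FALSE)
    files <- f
  } else {
    for (nm in names(result)) {
      obj <- result[[nm]]
      if (is.data.frame(obj)) {
        f <- paste0(base, "_", nm, ".csv")
        utils::write.csv(obj, f, row.names = FALSE)
        files <- c(files, f)
      }
    }
  }
  structure(list(experiment = plan$experiment,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 config_hash = rlang::hash(unclass(plan)),
                 seed = plan$seeds[1],
                 outputs = tibble::tibble(path = files,
                                          md5 = unname(tools::md5sum(files))),
                 result = result),
            class = "pet_run_record")
}

#' Consolidate run records into one report
#'
#' @param run_records List of `pet_run_record`s (at least one).
#' @param path Optional path of a JSON report to write.
#' @return A list: `runs` (tibble of experiment, timestamp, hash, seed, output
#'   counts), `conflicts` (experiments appearing with more than one config
#'   hash), and the per-run tabular `results`.
#' @export
make_report <- function(run_records, path = NULL) {
  if (length(run_records) == 0) stop("no run records", call. = FALSE)
  runs <- purrr::map_dfr(run_records, function(r)
    tibble::tibble(experiment = r$experiment, timestamp = r$timestamp,
                   config_hash = r$config_hash, seed = r$seed,
                   n_outputs = nrow(r$outputs)))
  conflicts <- runs |>
    dplyr::distinct(.data$experiment, .data$config_hash) |>
    dplyr::count(.data$experiment) |>
    dplyr::filter(.data$n > 1)
  results <- purrr::map(run_records, function(r)
    if (is.data.frame(r$result)) r$result else NULL)
  names(results) <- purrr::map_chr(run_records, "experiment")
  report <- list(runs = runs, conflicts = conflicts, results = results)
  if (!is.null(path))
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  report
}
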