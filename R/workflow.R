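# Three-phase experiment workflow: Phase 1 preprocessing chains per data
# type, Phase 2 model building with a (sub-models x epochs) hyperparameter
# grid, Phase 3 repeated evaluation on a fixed independent test set, plus
# classical comparators (random forest, gradient boosting, stacking).

#' Hyperparameter grid over sub-model counts and epochs
#'
#' The full sweep ranges sub-models over 5..50 and epochs over 50..500 in
#' steps of 50; reduced grids keep experiments desk-sized.
#'
#' @param n_submodels positive sorted integer vector.
#' @param epochs positive sorted integer vector.
#' @return a `grid_spec`.
#' @export
grid_spec <- function(n_submodels = seq(5L, 50L, by = 5L),
                      epochs = seq(50L, 500L, by = 50L)) {
  if (length(n_submodels) == 0 || length(epochs) == 0 ||
      any(n_submodels < 1) || any(epochs < 1) ||
      is.unsorted(n_submodels) || is.unsorted(epochs)) {
    abort_deepens("grid values must be positive and sorted", "deepens_config_error")
  }
  structure(list(n_submodels = as.integer(n_submodels),
                 epochs = as.integer(epochs)), class = "grid_spec")
}

#' Describe an end-to-end experiment
#'
#' Binds a data source (a generator spec), the split, the model family, the
#' CLU spec, the hyperparameter grid and the repetition count into one
#' reproducible description of a Phase 1 -> 3 run.
#'
#' @param data_type `"statistical"`, `"image"` or `"sequential"`.
#' @param generator the matching generator spec (see [preset_spec()]).
#' @param split a [split_spec()].
#' @param model `"dal"`, `"gdlb"`, `"desgel"`, `"single_clu"`, `"rf"`,
#'   `"gb"` or `"stack"`.
#' @param clu a [clu_spec()] for the neural models (regression variants are
#'   derived automatically for GDLB).
#' @param grid a [grid_spec()].
#' @param repetitions repeated fits per model in Phase 3 (default 10).
#' @param seed master seed.
#' @param image_size working image size for Phase 1 (default `c(32, 32)`;
#'   images are resized once to this shape).
#' @param daily_profile,minute_step sequential options: reduce each 7-day
#'   window to a 1440-minute daily profile, then keep every
#'   `minute_step`-th minute (defaults `TRUE` and 30, i.e. 48 steps).
#' @return an `experiment_config`.
#' @export
experiment_config <- function(data_type = c("statistical", "image", "sequential"),
                              generator = NULL,
                              split = split_spec(),
                              model = c("dal", "gdlb", "desgel", "single_clu",
                                        "rf", "gb", "stack"),
                              clu = NULL,
                              grid = grid_spec(5L, 50L),
                              repetitions = 10L,
                              seed = 1L,
                              image_size = c(32L, 32L),
                              daily_profile = TRUE,
                              minute_step = 30L) {
  data_type <- match.arg(data_type)
  model <- match.arg(model)
  if (is.null(generator)) {
    generator <- preset_spec(switch(data_type, statistical = "hdu_like",
                                    image = "xray_like",
                                    sequential = "depresjon_like"),
                             seed = seed)
  }
  expected <- switch(data_type, statistical = "statistical_gen_spec",
                     image = "image_gen_spec", sequential = "sequential_gen_spec")
  if (!inherits(generator, expected)) {
    abort_deepens(sprintf("generator (%s) does not match data_type '%s'",
                          class(generator)[1], data_type),
                  "deepens_config_error")
  }
  if (is.null(clu)) {
    clu <- switch(data_type,
      statistical = clu_spec("mlp", c(16L, 8L, 1L), epochs = 50L,
                             initial_lr = 0.01, batch_size = 32L, seed = seed),
      image = clu_spec("cnn", c(8L, 16L, 1L), epochs = 30L,
                       initial_lr = 0.005, batch_size = 16L, seed = seed),
      sequential = clu_spec("rnn", c(16L, 1L), epochs = 30L,
                            initial_lr = 0.01, batch_size = 16L, seed = seed))
  }
  if (clu$output_mode != "probability") {
    abort_deepens("configure the CLU as a probability classifier; GDLB derives",
                  "deepens_config_error")
  }
  structure(list(data_type = data_type, generator = generator, split = split,
                 model = model, clu = clu, grid = grid,
                 repetitions = as.integer(repetitions), seed = as.integer(seed),
                 image_size = as.integer(image_size),
                 daily_profile = isTRUE(daily_profile),
                 minute_step = as.integer(minute_step)),
            class = "experiment_config")
}

#' Derive the regression (booster) variant of a classifier CLU spec
#' @param spec a probability [clu_spec()].
#' @return the matching regression spec (MSE loss, SGD optimizer).
#' @export
as_regression_spec <- function(spec) {
  clu_spec(spec$kind, spec$layer_sizes, spec$activation,
           output_mode = "regression", loss = "mean_squared_error",
           optimizer = "sgd", initial_lr = spec$initial_lr,
           epochs = spec$epochs, batch_size = spec$batch_size,
           seed = spec$seed, lr_period = spec$lr_period, l2 = spec$l2,
           input_shape = spec$input_shape)
}

# ---- Phase 1 ----------------------------------------------------------------

#' Run Phase 1: data generation and preprocessing
#'
#' Applies the data-type-appropriate chain. Statistical: per-feature mean
#' imputation, train/val/test splitting, standard scaling fitted per fold
#' on its training rows, random-forest feature ranking on fold-1 training
#' data. Image: resize to the working size, split, and (for classical
#' comparators) CAE feature extraction fitted on each fold's training
#' images. Sequential: participant/time-of-day imputation, seven-day
#' moving-window generation, optional daily-profile reduction, split.
#' Every fitted transform (scaler, CAE, ranking) sees the training
#' partition only.
#'
#' @param config an [experiment_config()].
#' @param data optional pre-built dataset (otherwise generated from
#'   `config$generator`).
#' @return a `prepared_data` list with per-fold `train`/`val`/`test`
#'   x/y sets plus chain artefacts (`ranking`, `scalers`, `cae`, ...).
#' @export
run_phase1 <- function(config, data = NULL) {
  out <- list(config = config, type = config$data_type)
  if (config$data_type == "statistical") {
    tab <- if (is.null(data)) gen_statistical(config$generator) else data
    tab <- impute_feature_mean(tab)
    splits <- split_dataset(nrow(tab$values), config$split)
    scalers <- list()
    folds <- lapply(seq_along(splits), function(k) {
      s <- splits[[k]]
      scaler <- fit_standard_scaler(ft_rows(tab, s$train))
      scalers[[k]] <<- scaler
      sc <- apply_standard_scaler(scaler, tab)
      list(train = list(x = sc$values[s$train, , drop = FALSE], y = sc$labels[s$train]),
           val = list(x = sc$values[s$val, , drop = FALSE], y = sc$labels[s$val]),
           test = list(x = sc$values[s$test, , drop = FALSE], y = sc$labels[s$test]))
    })
    out$folds <- folds
    out$splits <- splits
    out$scalers <- scalers
    out$ranking <- rank_features_rf(
      feature_table(folds[[1]]$train$x, folds[[1]]$train$y),
      seed = config$seed)
  } else if (config$data_type == "image") {
    stack <- if (is.null(data)) gen_images(config$generator) else data
    stack <- resize_images(stack, c(config$image_size, 1L))
    arr <- stack_to_array(stack)
    splits <- split_dataset(length(stack$labels), config$split)
    need_cae <- config$model %in% c("rf", "gb", "stack")
    caes <- list()
    folds <- lapply(seq_along(splits), function(k) {
      s <- splits[[k]]
      fold <- list(
        train = list(x = arr[s$train, , , , drop = FALSE], y = stack$labels[s$train]),
        val = list(x = arr[s$val, , , , drop = FALSE], y = stack$labels[s$val]),
        test = list(x = arr[s$test, , , , drop = FALSE], y = stack$labels[s$test]))
      if (need_cae) {
        sub <- function(i) image_stack(stack$images[i], stack$labels[i])
        cae <- cae_fit(sub(s$train), bottleneck_dim = 16L, epochs = 8L,
                       seed = config$seed + k)
        caes[[k]] <<- cae
        fold$features <- list(
          train = cae_extract(cae, sub(s$train)),
          val = cae_extract(cae, sub(s$val)),
          test = cae_extract(cae, sub(s$test)))
      }
      fold
    })
    out$folds <- folds
    out$splits <- splits
    out$cae <- caes
  } else {
    rec <- if (is.null(data)) gen_sequential(config$generator) else data
    rec <- impute_participant_time_mean(rec)
    ws <- generate_windows(rec, daily_profile = config$daily_profile)
    x <- ws$values
    if (config$minute_step > 1L) {
      x <- x[, seq(1L, ncol(x), by = config$minute_step), drop = FALSE]
    }
    splits <- split_dataset(nrow(x), config$split)
    folds <- lapply(splits, function(s) {
      list(train = list(x = x[s$train, , drop = FALSE], y = ws$meta$label[s$train]),
           val = list(x = x[s$val, , drop = FALSE], y = ws$meta$label[s$val]),
           test = list(x = x[s$test, , drop = FALSE], y = ws$meta$label[s$test]))
    })
    out$folds <- folds
    out$splits <- splits
    out$windows <- ws$meta
  }
  class(out) <- "prepared_data"
  out
}

#' @export
print.prepared_data <- function(x, ...) {
  f <- x$folds[[1]]
  cat(sprintf("<prepared_data> %s: %d folds, sizes %d/%d/%d\n", x$type,
              length(x$folds), NROW(f$train$y), NROW(f$val$y), NROW(f$test$y)))
  invisible(x)
}

# ---- model fitting (neural + classical) -------------------------------------

# classical models consume flat feature matrices; images go through the CAE
baseline_xy <- function(fold, which) {
  if (!is.null(fold$features)) {
    ft <- fold$features[[which]]
    list(x = ft$values, y = ft$labels)
  } else {
    d <- fold[[which]]
    x <- d$x
    if (length(dim(x)) > 2) dim(x) <- c(dim(x)[1], prod(dim(x)[-1]))
    list(x = x, y = d$y)
  }
}

fit_workflow_model <- function(config, fold, model = config$model,
                               n_submodels = config$grid$n_submodels[1],
                               epochs = config$grid$epochs[1],
                               seed = config$seed) {
  clu <- config$clu
  clu$epochs <- as.integer(epochs)
  clu$seed <- as.integer(seed)
  if (model %in% c("dal", "gdlb", "desgel", "single_clu")) {
    tr <- fold$train; va <- fold$val
    fit <- switch(model,
      dal = fit_dal(tr, va, clu, n_members = n_submodels, seed = seed),
      desgel = fit_desgel(tr, va, clu, n_members = n_submodels, seed = seed),
      gdlb = fit_gdlb(tr, va, as_regression_spec(clu),
                      n_boosters = n_submodels, seed = seed),
      single_clu = train_clu(build_clu(clu), tr, va)$clu)
    return(fit)
  }
  tr <- baseline_xy(fold, "train")
  if (model == "rf") {
    with_rng_seed(seed, randomForest::randomForest(
      x = tr$x, y = factor(tr$y, levels = c(0, 1)), ntree = 100L))
  } else if (model == "gb") {
    with_rng_seed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3L, eta = 0.3,
                    nthread = 1L),
      data = xgboost::xgb.DMatrix(tr$x, label = tr$y), nrounds = 50L,
      verbose = 0))
  } else if (model == "stack") {
    rf <- with_rng_seed(seed, randomForest::randomForest(
      x = tr$x, y = factor(tr$y, levels = c(0, 1)), ntree = 100L))
    gb <- with_rng_seed(seed + 1L, xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3L, eta = 0.3,
                    nthread = 1L),
      data = xgboost::xgb.DMatrix(tr$x, label = tr$y), nrounds = 50L,
      verbose = 0))
    va <- baseline_xy(fold, "val")
    meta <- cbind(rf = predict(rf, va$x, type = "prob")[, "1"],
                  gb = predict(gb, xgboost::xgb.DMatrix(va$x)))
    meta_df <- as.data.frame(meta)
    lr <- suppressWarnings(stats::glm(y ~ ., data = cbind(meta_df, y = va$y),
                                      family = stats::binomial()))
    structure(list(rf = rf, gb = gb, lr = lr), class = "stack_baseline")
  } else {
    abort_deepens(paste0("unknown model: ", model), "deepens_config_error")
  }
}

predict_workflow_model <- function(config, fitted, fold, which = "test",
                                   model = config$model) {
  if (model %in% c("dal", "gdlb", "desgel", "single_clu")) {
    x <- fold[[which]]$x
    scores <- switch(model,
      dal = predict_dal(fitted, x)$scores,
      gdlb = predict_gdlb(fitted, x)$scores,
      desgel = predict_desgel(fitted, x)$scores,
      single_clu = predict_proba(fitted, x))
    return(scores)
  }
  d <- baseline_xy(fold, which)
  if (inherits(fitted, "randomForest")) {
    predict(fitted, d$x, type = "prob")[, "1"]
  } else if (inherits(fitted, "stack_baseline")) {
    meta <- data.frame(rf = predict(fitted$rf, d$x, type = "prob")[, "1"],
                       gb = predict(fitted$gb, xgboost::xgb.DMatrix(d$x)))
    as.numeric(stats::predict(fitted$lr, meta, type = "response"))
  } else {
    predict(fitted, xgboost::xgb.DMatrix(d$x))
  }
}

# ---- Phase 2 ----------------------------------------------------------------

#' Run Phase 2: grid search over sub-model counts and epochs
#'
#' Fits the configured model at every grid point on fold 1 and scores it on
#' the validation partition; the point with the best validation accuracy
#' wins (ties broken toward fewer sub-models, then fewer epochs). Returns
#' the refit best model and the tuning table.
#'
#' @param config an [experiment_config()].
#' @param prep output of [run_phase1()].
#' @param fold fold index used for tuning (default 1).
#' @return list with `model`, `best` (row of the tuning table) and
#'   `tuning_table` (n_submodels, epochs, val_accuracy).
#' @export
run_phase2_grid <- function(config, prep, fold = 1L) {
  fd <- prep$folds[[fold]]
  pts <- expand.grid(n_submodels = config$grid$n_submodels,
                     epochs = config$grid$epochs)
  if (nrow(pts) == 0) abort_deepens("empty grid", "deepens_config_error")
  acc <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    fit <- fit_workflow_model(config, fd, n_submodels = pts$n_submodels[i],
                              epochs = pts$epochs[i])
    sc <- predict_workflow_model(config, fit, fd, "val")
    acc[i] <- mean((sc >= 0.5) == fd$val$y)
  }
  tab <- cbind(pts, val_accuracy = acc)
  ord <- order(-tab$val_accuracy, tab$n_submodels, tab$epochs)
  best <- tab[ord[1], ]
  model <- fit_workflow_model(config, fd, n_submodels = best$n_submodels,
                              epochs = best$epochs)
  list(model = model, best = best, tuning_table = tab)
}

# ---- Phase 3 ----------------------------------------------------------------

#' Run Phase 3: repeated evaluation and model comparison
#'
#' For every model family, refits `repetitions` times (repetition r uses
#' train/validation fold `1 + (r-1) mod folds` and seed `seed + 101*r`) and
#' evaluates on the fixed independent test partition; per-metric means and
#' standard deviations are reported as `"m ± d"`, together with group
#' averages of the proposed (DAL/GDLB/DeSGEL) and traditional
#' (single CLU/RF/GB/stack) families.
#'
#' @param config an [experiment_config()] (its `model` field is ignored
#'   here).
#' @param prep output of [run_phase1()]; for image data, CAE features must
#'   be present if classical models are requested.
#' @param models character vector of model families to compare.
#' @param repetitions overrides `config$repetitions` when given.
#' @return a `comparison_report`: `summaries` (named list of
#'   `summary_report`), `group_means` (data.frame), `text` (grid lines).
#' @export
run_phase3_compare <- function(config, prep,
                               models = c("dal", "gdlb", "desgel",
                                          "single_clu", "rf", "gb", "stack"),
                               repetitions = NULL) {
  if (length(models) == 0) abort_deepens("no models to compare", "deepens_config_error")
  R <- if (is.null(repetitions)) config$repetitions else as.integer(repetitions)
  nf <- length(prep$folds)
  summaries <- list()
  means <- list()
  for (m in models) {
    reports <- lapply(seq_len(R), function(r) {
      fd <- prep$folds[[1L + (r - 1L) %% nf]]
      fit <- fit_workflow_model(config, fd, model = m,
                                seed = config$seed + 101L * r)
      sc <- predict_workflow_model(config, fit, fd, "test", model = m)
      evaluate_predictions(fd$test$y, sc)
    })
    summaries[[m]] <- if (R >= 2) summarize_repeats(reports) else {
      one <- reports[[1]]
      df <- data.frame(metric = names(unclass(one)),
                       mean = unlist(unclass(one)), sd = 0)
      df$formatted <- mapply(format_m_pm_d, df$mean, df$sd)
      attr(df, "n_repeats") <- 1L
      class(df) <- c("summary_report", "data.frame")
      df
    }
    means[[m]] <- stats::setNames(summaries[[m]]$mean, summaries[[m]]$metric)
  }
  proposed <- intersect(models, c("dal", "gdlb", "desgel"))
  traditional <- intersect(models, c("single_clu", "rf", "gb", "stack"))
  group_row <- function(group) {
    if (!length(group)) return(NULL)
    colMeans(do.call(rbind, means[group]))
  }
  gm <- list(proposed = group_row(proposed), traditional = group_row(traditional))
  gm <- gm[!vapply(gm, is.null, TRUE)]
  group_means <- if (length(gm)) {
    data.frame(group = names(gm), do.call(rbind, gm), row.names = NULL)
  } else data.frame()
  grid_summaries <- summaries
  for (g in names(gm)) {
    df <- data.frame(metric = names(gm[[g]]), mean = as.numeric(gm[[g]]),
                     sd = NA_real_,
                     formatted = sprintf("%.2f", round(as.numeric(gm[[g]]), 2)))
    class(df) <- c("summary_report", "data.frame")
    grid_summaries[[paste0("average_", g)]] <- df
  }
  structure(list(summaries = summaries, group_means = group_means,
                 models = models, repetitions = R,
                 text = format_comparison_grid(grid_summaries)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Write a comparison report (CSV + text grid)
#' @param report a `comparison_report`.
#' @param dir output directory.
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(report$summaries), function(nm) {
    cbind(model = nm, as.data.frame(report$summaries[[nm]]))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "comparison.csv"),
                   row.names = FALSE)
  if (nrow(report$group_means)) {
    utils::write.csv(report$group_means, file.path(dir, "group_means.csv"),
                     row.names = FALSE)
  }
  writeLines(report$text, file.path(dir, "comparison.txt"))
  invisible(dir)
}
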