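# The three deep-ensemble meta-algorithms over pluggable CLUs:
#   DAL    - bootstrap-aggregated neural classifiers, mean of member scores
#   GDLB   - gradient boosting with neural regression boosters on residuals,
#            each booster's output scaled by a learning rate in (0, 1)
#   DeSGEL - two-level stacking: level-0 neural classifiers produce a
#            metadata matrix of scores on held-out rows; a level-1
#            classifier makes the final prediction from it.

#' Scores and thresholded classes for a batch of inputs
#'
#' @param scores numeric scores in \[0, 1\].
#' @param threshold class threshold (default 0.5); `classes = scores >= threshold`.
#' @param raw optional unclipped scores (GDLB).
#' @return an object of class `prediction_vector` with fields `scores`,
#'   `classes`, `threshold` (and `raw` when supplied).
#' @export
prediction_vector <- function(scores, threshold = 0.5, raw = NULL) {
  structure(list(scores = scores,
                 classes = as.integer(scores >= threshold),
                 threshold = threshold,
                 raw = raw),
            class = "prediction_vector")
}

#' @export
print.prediction_vector <- function(x, ...) {
  cat(sprintf("<prediction_vector> n=%d, %d positive at threshold %.2f\n",
              length(x$scores), sum(x$classes), x$threshold))
  invisible(x)
}

member_spec <- function(clu_spec, seed_offset) {
  s <- clu_spec
  s$seed <- s$seed + as.integer(seed_offset)
  s
}

as_xy <- function(data) {
  if (inherits(data, "feature_table")) list(x = data$values, y = data$labels)
  else if (inherits(data, "window_set")) list(x = data$values, y = data$meta$label)
  else data
}

# ---- DAL: deep aggregated learning -----------------------------------------

#' Fit a deep aggregated learning (bagging) ensemble
#'
#' Trains `n_members` CLUs, each on its own bootstrap resample of the
#' training set (size equal to the training set, drawn with replacement),
#' validated against the shared validation set. Members differ only by
#' their resample and a seed offset (member i uses `seed + i - 1`). The
#' ensemble score is the mean of member probabilities.
#'
#' @param train,val lists with `x`/`y` (or `feature_table`/`window_set`).
#' @param clu_spec a probability-output [clu_spec()].
#' @param n_members number of member CLUs (>= 1).
#' @param seed base seed; also seeds the bootstrap draws.
#' @param subset_mode `"bootstrap"` (default), `"full"` (every member sees
#'   the whole training set) or `"disjoint"` (equal random partition).
#' @param aggregator `"mean"` (default) or `"mode"` (majority vote on
#'   thresholded classes; ties go to the positive class).
#' @param threshold class threshold (default 0.5).
#' @return a `dal_model`.
#' @export
fit_dal <- function(train, val, clu_spec, n_members, seed = clu_spec$seed,
                    subset_mode = c("bootstrap", "full", "disjoint"),
                    aggregator = c("mean", "mode"), threshold = 0.5) {
  subset_mode <- match.arg(subset_mode)
  aggregator <- match.arg(aggregator)
  if (n_members < 1) abort_deepens("n_members must be >= 1", "deepens_config_error")
  if (clu_spec$output_mode != "probability") {
    abort_deepens("DAL members must have output_mode = 'probability'",
                  "deepens_config_error")
  }
  train <- as_xy(train); val <- as_xy(val)
  n <- NROW(train$y)
  assignments <- with_rng_seed(seed + 1000003L, {
    switch(subset_mode,
      full = replicate(n_members, seq_len(n), simplify = FALSE),
      bootstrap = replicate(n_members, sort(sample.int(n, n, replace = TRUE)),
                            simplify = FALSE),
      disjoint = {
        perm <- sample.int(n)
        split(perm, rep_len(seq_len(n_members), n))
      })
  })
  members <- vector("list", n_members)
  logs <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    idx <- assignments[[i]]
    if (length(idx) < clu_spec$batch_size && length(idx) < n) {
      abort_deepens(sprintf("member %d subset (%d) smaller than one batch (%d)",
                            i, length(idx), clu_spec$batch_size),
                    "deepens_config_error")
    }
    sp <- member_spec(clu_spec, i - 1L + (seed - clu_spec$seed))
    fit <- train_clu(build_clu(sp),
                     list(x = subset_x(sp, train$x, idx), y = train$y[idx]),
                     val)
    members[[i]] <- fit$clu
    logs[[i]] <- fit$log
  }
  new_dal_model(members, aggregator = aggregator, threshold = threshold,
                subset_assignments = assignments, logs = logs, seed = seed)
}

#' Assemble a DAL model from already fitted members
#'
#' @param members list of fitted probability CLUs.
#' @param aggregator `"mean"` or `"mode"`.
#' @param threshold class threshold.
#' @param subset_assignments,logs,seed optional provenance.
#' @return a `dal_model`.
#' @export
new_dal_model <- function(members, aggregator = "mean", threshold = 0.5,
                          subset_assignments = NULL, logs = NULL, seed = NULL) {
  if (length(members) < 1) abort_deepens("need >= 1 member", "deepens_config_error")
  structure(list(members = members, aggregator = aggregator,
                 threshold = threshold, subset_assignments = subset_assignments,
                 logs = logs, seed = seed),
            class = "dal_model")
}

subset_x <- function(spec, x, idx) {
  if (inherits(x, "feature_table")) x <- x$values
  clu_slice(spec, clu_coerce_x(spec, x)$x, idx)
}

#' Predict with a DAL ensemble
#'
#' The score of each row is the running sum of member probabilities divided
#' by the member count (the bagging mean); with `aggregator = "mode"` the
#' score is the share of members voting positive, ties resolved to the
#' positive class.
#'
#' @param model a `dal_model`.
#' @param inputs matrix/array/`feature_table` of rows to score.
#' @return a [prediction_vector()].
#' @export
predict_dal <- function(model, inputs) {
  n <- length(model$members)
  acc <- NULL
  for (m in model$members) {
    p <- predict_proba(m, inputs)
    if (model$aggregator == "mode") p <- as.numeric(p >= model$threshold)
    acc <- if (is.null(acc)) p else acc + p
  }
  score <- acc / n
  if (model$aggregator == "mode") {
    prediction_vector(score, threshold = 0.5)
  } else {
    prediction_vector(score, threshold = model$threshold)
  }
}

# ---- GDLB: gradient deep-learning boosting ---------------------------------

#' Fit a gradient deep-learning boosting ensemble
#'
#' Starts from the base prediction `P_base = mean(train labels)`. Booster i
#' is a regression CLU fitted to the residuals `labels - current
#' prediction`; its output, scaled by a learning rate `lambda_i` in (0, 1),
#' is added to the running prediction. Residuals therefore shrink over the
#' booster sequence.
#'
#' @param train,val lists with `x`/`y` (or containers).
#' @param clu_spec a regression [clu_spec()] (mean-squared-error loss, SGD).
#' @param n_boosters number of boosters (>= 1).
#' @param lr_policy `"uniform"` (one uniform(0,1) draw per booster, seeded)
#'   or a fixed numeric learning rate (recycled over boosters).
#' @param seed base seed.
#' @param threshold class threshold on the clipped score (default 0.5).
#' @param booster_fitter optional function `(x, residuals, i) -> function(x)`
#'   replacing the CLU booster (used to study the boosting recursion with
#'   idealised boosters).
#' @return a `gdlb_model` with the staged training MSE in `staged_mse`
#'   (element 1 = after the base prediction alone).
#' @export
fit_gdlb <- function(train, val, clu_spec, n_boosters, lr_policy = "uniform",
                     seed = clu_spec$seed, threshold = 0.5,
                     booster_fitter = NULL) {
  if (n_boosters < 1) abort_deepens("n_boosters must be >= 1", "deepens_config_error")
  if (is.null(booster_fitter)) {
    if (clu_spec$output_mode != "regression") {
      abort_deepens("GDLB boosters must have output_mode = 'regression'",
                    "deepens_config_error")
    }
  }
  train <- as_xy(train); val <- as_xy(val)
  y <- as.numeric(train$y); yv <- as.numeric(val$y)
  p_base <- mean(y)
  current <- rep(p_base, length(y))
  val_current <- rep(p_base, length(yv))
  lambdas <- if (is.numeric(lr_policy)) {
    rep_len(lr_policy, n_boosters)
  } else {
    with_rng_seed(seed + 7919L, stats::runif(n_boosters))
  }
  if (any(lambdas <= 0 | lambdas > 1)) {
    abort_deepens("booster learning rates must lie in (0, 1]", "deepens_config_error")
  }
  boosters <- vector("list", n_boosters)
  staged <- numeric(n_boosters + 1)
  staged[1] <- mean((y - current)^2)
  for (i in seq_len(n_boosters)) {
    resid <- y - current
    if (is.null(booster_fitter)) {
      sp <- member_spec(clu_spec, i - 1L + (seed - clu_spec$seed))
      fit <- train_clu(build_clu(sp), list(x = train$x, y = resid),
                       list(x = val$x, y = yv - val_current))
      boosters[[i]] <- fit$clu
      out <- predict_proba(fit$clu, train$x)
      val_out <- predict_proba(fit$clu, val$x)
    } else {
      f <- booster_fitter(train$x, resid, i)
      boosters[[i]] <- f
      out <- f(train$x)
      val_out <- f(val$x)
    }
    current <- current + lambdas[i] * out
    val_current <- val_current + lambdas[i] * val_out
    staged[i + 1] <- mean((y - current)^2)
  }
  structure(list(p_base = p_base, boosters = boosters, lambdas = lambdas,
                 threshold = threshold, staged_mse = staged, seed = seed),
            class = "gdlb_model")
}

#' Predict with a GDLB ensemble
#'
#' The raw score is `P_base + sum_i lambda_i * O_i(inputs)`; the reported
#' score clips it to \[0, 1\] and the class thresholds it.
#'
#' @param model a `gdlb_model`.
#' @param inputs rows to score.
#' @return a [prediction_vector()] (field `raw` holds the unclipped score).
#' @export
predict_gdlb <- function(model, inputs) {
  raw <- NULL
  for (i in seq_along(model$boosters)) {
    b <- model$boosters[[i]]
    out <- if (inherits(b, "clu")) predict_proba(b, inputs) else b(inputs)
    contrib <- model$lambdas[i] * out
    raw <- if (is.null(raw)) model$p_base + contrib else raw + contrib
  }
  if (is.null(raw)) {
    n <- if (inherits(inputs, "feature_table")) nrow(inputs$values)
         else if (is.null(dim(inputs))) length(inputs) else dim(inputs)[1]
    raw <- rep(model$p_base, n)
  }
  prediction_vector(pmin(pmax(raw, 0), 1), threshold = model$threshold, raw = raw)
}

# ---- DeSGEL: deep stacked generalisation -----------------------------------

#' Build the stacking metadata matrix
#'
#' Column i is `predict_proba` of level-0 member i on `inputs`, in member
#' order.
#'
#' @param level0 list of fitted CLUs.
#' @param inputs rows to score.
#' @return an `n x length(level0)` numeric matrix.
#' @export
build_metadata <- function(level0, inputs) {
  if (length(level0) < 1) abort_deepens("no level-0 members", "deepens_config_error")
  cols <- vector("list", length(level0))
  for (i in seq_along(level0)) cols[[i]] <- predict_proba(level0[[i]], inputs)
  do.call(cbind, cols)
}

#' Fit a deep stacked generalisation ensemble
#'
#' Trains `n_members` level-0 probability CLUs on the full training set
#' (differing by seed offset) and fits the level-1 classifier on a
#' metadata matrix of member scores computed on rows the scoring member
#' never saw during training. With `metadata = "oof"` (default) the
#' metadata is built by out-of-fold prediction: the training set is split
#' into `oof_folds` folds and, for each member, a clone is refit with each
#' fold held out to score it, so every training row gets a leakage-free
#' score from every member. With `metadata = "validation"` the members'
#' scores on the validation split are used instead (cheaper, but the
#' metadata is only as tall as the validation split).
#'
#' @param train,val lists with `x`/`y` (or containers); `val` is the
#'   checkpointing set for every CLU fit.
#' @param clu_spec a probability [clu_spec()] for the level-0 members.
#' @param n_members number of level-0 members (>= 1).
#' @param level1_spec the meta-learner: `NULL` for the default
#'   single-sigmoid-unit CLU over the n member scores (logistic
#'   regression), a [clu_spec()], or a function `(metadata) -> scores`
#'   used as a fixed meta-learner.
#' @param seed base seed (member i uses `seed + i - 1`).
#' @param threshold class threshold (default 0.5).
#' @param metadata `"oof"` or `"validation"` (see above).
#' @param oof_folds folds for out-of-fold metadata (default 3).
#' @return a `desgel_model`.
#' @export
fit_desgel <- function(train, val, clu_spec, n_members, level1_spec = NULL,
                       seed = clu_spec$seed, threshold = 0.5,
                       metadata = c("oof", "validation"), oof_folds = 3L) {
  metadata <- match.arg(metadata)
  if (n_members < 1) abort_deepens("n_members must be >= 1", "deepens_config_error")
  if (clu_spec$output_mode != "probability") {
    abort_deepens("DeSGEL level-0 members must have output_mode = 'probability'",
                  "deepens_config_error")
  }
  train <- as_xy(train); val <- as_xy(val)
  level0 <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    sp <- member_spec(clu_spec, i - 1L + (seed - clu_spec$seed))
    level0[[i]] <- train_clu(build_clu(sp), train, val)$clu
  }
  n <- NROW(train$y)
  if (metadata == "oof") {
    fold_id <- with_rng_seed(seed + 500009L, sample(rep_len(seq_len(oof_folds), n)))
    meta <- matrix(NA_real_, n, n_members)
    for (i in seq_len(n_members)) {
      sp <- member_spec(clu_spec, i - 1L + (seed - clu_spec$seed))
      for (f in seq_len(oof_folds)) {
        hold <- which(fold_id == f)
        clone <- train_clu(build_clu(sp),
                           list(x = subset_x(sp, train$x, setdiff(seq_len(n), hold)),
                                y = train$y[-hold]),
                           val)$clu
        meta[hold, i] <- predict_proba(clone, subset_x(sp, train$x, hold))
      }
    }
    meta_y <- train$y
  } else {
    meta <- build_metadata(level0, val$x)
    meta_y <- val$y
  }
  if (nrow(meta) < 2) {
    abort_deepens("too few metadata rows to fit the level-1 classifier",
                  "deepens_input_error")
  }
  level1 <- if (is.function(level1_spec)) {
    level1_spec
  } else {
    # default meta-learner: logistic regression over the member scores —
    # deliberately low-capacity, as in classical stacked generalisation
    sp1 <- if (is.null(level1_spec)) {
      clu_spec("mlp", 1L, epochs = 100L, batch_size = 16L,
               initial_lr = 0.05, l2 = 0.01, seed = seed + 100003L)
    } else level1_spec
    if (sp1$output_mode != "probability") {
      abort_deepens("level-1 classifier must output probabilities",
                    "deepens_config_error")
    }
    train_clu(build_clu(sp1), list(x = meta, y = meta_y),
              list(x = meta, y = meta_y))$clu
  }
  new_desgel_model(level0, level1, threshold = threshold, seed = seed)
}

#' Assemble a DeSGEL model from fitted parts
#'
#' @param level0 list of fitted probability CLUs.
#' @param level1 a fitted CLU over the metadata, or a function
#'   `(metadata) -> scores`.
#' @param threshold class threshold.
#' @param seed optional provenance.
#' @return a `desgel_model`.
#' @export
new_desgel_model <- function(level0, level1, threshold = 0.5, seed = NULL) {
  if (length(level0) < 1) abort_deepens("need >= 1 level-0 member",
                                        "deepens_config_error")
  structure(list(level0 = level0, level1 = level1, threshold = threshold,
                 seed = seed),
            class = "desgel_model")
}

#' Predict with a DeSGEL ensemble
#'
#' Scores are `f(metadata)` where `f` is the level-1 classifier and the
#' metadata columns are the level-0 member scores on `inputs`.
#'
#' @param model a `desgel_model`.
#' @param inputs rows to score.
#' @return a [prediction_vector()].
#' @export
predict_desgel <- function(model, inputs) {
  meta <- build_metadata(model$level0, inputs)
  scores <- if (is.function(model$level1)) model$level1(meta)
            else predict_proba(model$level1, meta)
  prediction_vector(scores, threshold = model$threshold)
}

#' @export
print.dal_model <- function(x, ...) {
  cat(sprintf("<dal_model> %d members, aggregator=%s, threshold=%.2f\n",
              length(x$members), x$aggregator, x$threshold))
  invisible(x)
}

#' @export
print.gdlb_model <- function(x, ...) {
  cat(sprintf("<gdlb_model> P_base=%.4f, %d boosters, lambdas in [%.3f, %.3f]\n",
              x$p_base, length(x$boosters), min(x$lambdas), max(x$lambdas)))
  invisible(x)
}

#' @export
print.desgel_model <- function(x, ...) {
  cat(sprintf("<desgel_model> %d level-0 members, level-1 %s\n",
              length(x$level0),
              if (is.function(x$level1)) "function" else "CLU"))
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

#' Save / load a fitted ensemble to a directory
#'
#' Writes a `manifest.yaml` (type, member count, thresholds, learning rates,
#' base prediction, seeds) plus one serialized member per file; predictions
#' can be exported with [write_predictions()].
#'
#' @param model a `dal_model`, `gdlb_model` or `desgel_model`.
#' @param dir directory to create.
#' @export
save_ensemble <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  type <- class(model)[1]
  manifest <- list(type = type, threshold = model$threshold, seed = model$seed)
  if (type == "dal_model") {
    manifest$n_members <- length(model$members)
    manifest$aggregator <- model$aggregator
  } else if (type == "gdlb_model") {
    manifest$n_boosters <- length(model$boosters)
    manifest$p_base <- model$p_base
    manifest$lambdas <- model$lambdas
  } else {
    manifest$n_members <- length(model$level0)
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_ensemble
#' @param dir directory containing a saved ensemble.
#' @export
load_ensemble <- function(dir) readRDS(file.path(dir, "model.rds"))

#' Export predictions as CSV (row_id, score, class)
#' @param pred a [prediction_vector()].
#' @param path file path.
#' @export
write_predictions <- function(pred, path) {
  utils::write.csv(data.frame(row_id = seq_along(pred$scores),
                              score = pred$scores, class = pred$classes),
                   path, row.names = FALSE)
  invisible(path)
}
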