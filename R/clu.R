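# Core learning units (CLUs): the pluggable neural base learners used by all
# three deep-ensemble methods. A CLU is specified declaratively (clu_spec),
# built unfitted (build_clu), and trained with step-decay learning rate and
# best-validation-loss checkpointing (train_clu).

abort_deepens <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "deepens_error")))
}

#' Specify a core learning unit
#'
#' A CLU is the neural sub-model plugged into each deep ensemble: a
#' multilayer perceptron for tabular data (`kind = "mlp"`), a small
#' convolution--pooling network for images (`"cnn"`), or a gated recurrent
#' layer with additive attention pooling for minute-level sequences
#' (`"rnn"`). The spec fully determines the network, its initialisation
#' (via `seed`) and its training schedule.
#'
#' Classifier members (`output_mode = "probability"`) train with binary
#' cross-entropy and a sigmoid output; boosting members
#' (`output_mode = "regression"`) train with mean squared error and a linear
#' output. The two pairings are enforced.
#'
#' @param kind one of `"mlp"`, `"cnn"`, `"rnn"`.
#' @param layer_sizes positive integers ending in 1 (the output width).
#'   For `mlp`: widths of the dense layers. For `cnn`: filter counts of the
#'   3x3 conv + 2x2 max-pool blocks, then the output. For `rnn`: recurrent
#'   units, then the output.
#' @param activation hidden activation (`"relu"`, `"tanh"`, `"sigmoid"`).
#' @param output_mode `"probability"` or `"regression"`.
#' @param loss `"binary_cross_entropy"` or `"mean_squared_error"`; defaults
#'   to the one matching `output_mode`.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param initial_lr initial learning rate (decayed by 10% every
#'   `lr_period` epochs).
#' @param epochs,batch_size training schedule.
#' @param seed integer controlling initialisation and batch shuffling.
#' @param lr_period epochs between learning-rate decay steps (default 50).
#' @param l2 L2 weight-decay coefficient applied to weight matrices (not
#'   biases) during training; default 0.
#' @param input_shape optional input shape (features for `mlp`;
#'   `c(h, w, channels)` for `cnn`; `c(timesteps, channels)` for `rnn`).
#'   If `NULL` it is inferred from the first data seen.
#' @return an object of class `clu_spec`.
#' @export
clu_spec <- function(kind = c("mlp", "cnn", "rnn"),
                     layer_sizes = NULL,
                     activation = "relu",
                     output_mode = c("probability", "regression"),
                     loss = NULL,
                     optimizer = NULL,
                     initial_lr = 0.01,
                     epochs = 100L,
                     batch_size = 32L,
                     seed = 1L,
                     lr_period = 50L,
                     l2 = 0,
                     input_shape = NULL) {
  if (length(kind) != 1 || !kind %in% c("mlp", "cnn", "rnn")) {
    abort_deepens(paste0("unknown CLU kind: ", paste(kind, collapse = "/")),
                  "deepens_config_error")
  }
  output_mode <- match.arg(output_mode)
  if (is.null(layer_sizes)) {
    layer_sizes <- switch(kind,
      mlp = c(64L, 32L, 1L),
      cnn = c(16L, 32L, 64L, 1L),
      rnn = c(64L, 1L))
  }
  if (length(layer_sizes) == 0 || any(layer_sizes < 1) ||
      any(layer_sizes != round(layer_sizes))) {
    abort_deepens("layer_sizes must be a non-empty vector of positive integers",
                  "deepens_config_error")
  }
  if (utils::tail(layer_sizes, 1) != 1L) {
    abort_deepens("output layer width must be 1 for binary tasks",
                  "deepens_config_error")
  }
  if (kind == "rnn" && length(layer_sizes) != 2) {
    abort_deepens("rnn layer_sizes must be c(units, 1)", "deepens_config_error")
  }
  if (!activation %in% c("relu", "tanh", "sigmoid")) {
    abort_deepens(paste0("unknown activation: ", activation), "deepens_config_error")
  }
  expected_loss <- if (output_mode == "probability") "binary_cross_entropy"
                   else "mean_squared_error"
  if (is.null(loss)) loss <- expected_loss
  if (!loss %in% c("binary_cross_entropy", "mean_squared_error")) {
    abort_deepens(paste0("unknown loss: ", loss), "deepens_config_error")
  }
  if (loss != expected_loss) {
    abort_deepens(paste0("loss '", loss, "' is incompatible with output_mode '",
                         output_mode, "'"), "deepens_config_error")
  }
  if (is.null(optimizer)) {
    optimizer <- if (output_mode == "probability") "adam" else "sgd"
  }
  if (!optimizer %in% c("adam", "sgd")) {
    abort_deepens(paste0("unknown optimizer: ", optimizer), "deepens_config_error")
  }
  if (!is.numeric(initial_lr) || initial_lr <= 0) {
    abort_deepens("initial_lr must be positive", "deepens_config_error")
  }
  stopifnot(epochs >= 1, batch_size >= 1, lr_period >= 1, l2 >= 0)
  structure(list(kind = kind,
                 layer_sizes = as.integer(layer_sizes),
                 activation = activation,
                 output_mode = output_mode,
                 loss = loss,
                 optimizer = optimizer,
                 initial_lr = initial_lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 lr_period = as.integer(lr_period),
                 l2 = l2,
                 input_shape = if (is.null(input_shape)) NULL else as.integer(input_shape)),
            class = "clu_spec")
}

#' @export
print.clu_spec <- function(x, ...) {
  cat(sprintf("<clu_spec> %s [%s] %s/%s %s lr=%g epochs=%d batch=%d seed=%d\n",
              x$kind, paste(x$layer_sizes, collapse = ","), x$output_mode,
              x$loss, x$optimizer, x$initial_lr, x$epochs, x$batch_size, x$seed))
  invisible(x)
}

# ---- parameter initialisation ----------------------------------------------

clu_init_params <- function(spec, input_shape) {
  with_rng_seed(spec$seed, {
    if (spec$kind == "mlp") {
      sizes <- c(input_shape[1], spec$layer_sizes)
      lapply(seq_len(length(sizes) - 1),
             function(i) dense_init(sizes[i], sizes[i + 1]))
    } else if (spec$kind == "cnn") {
      filt <- spec$layer_sizes[-length(spec$layer_sizes)]
      h <- input_shape[1]; w <- input_shape[2]; cin <- input_shape[3]
      layers <- list()
      for (f in filt) {
        layers[[length(layers) + 1]] <- conv_init(3L, cin, f)
        cin <- f
        h <- h %/% 2L; w <- w %/% 2L
      }
      if (h < 1 || w < 1) {
        abort_deepens("image too small for the configured number of conv blocks",
                      "deepens_config_error")
      }
      list(conv = layers, head = dense_init(h * w * cin, 1L),
           spatial = c(h, w, cin))
    } else {
      units <- spec$layer_sizes[1]
      list(gru = gru_init(input_shape[2], units),
           head = dense_init(units, 1L))
    }
  })
}

#' Build an unfitted CLU from a spec
#'
#' Parameter initialisation is fully determined by `spec$seed` (and the
#' input shape); building the same spec twice yields identical parameters.
#'
#' @param spec a [clu_spec()].
#' @return an object of class `clu`, unfitted.
#' @export
build_clu <- function(spec) {
  if (!inherits(spec, "clu_spec")) {
    abort_deepens("build_clu expects a clu_spec", "deepens_config_error")
  }
  params <- if (!is.null(spec$input_shape)) {
    clu_init_params(spec, clu_norm_shape(spec, spec$input_shape))
  }
  structure(list(spec = spec, parameters = params, is_fitted = FALSE,
                 input_shape = spec$input_shape),
            class = "clu")
}

#' @export
print.clu <- function(x, ...) {
  cat(sprintf("<clu> %s (%s)\n", x$spec$kind,
              if (x$is_fitted) "fitted" else "unfitted"))
  invisible(x)
}

clu_norm_shape <- function(spec, shape) {
  shape <- as.integer(shape)
  if (spec$kind == "mlp" && length(shape) == 1) return(shape)
  if (spec$kind == "cnn") {
    if (length(shape) == 2) shape <- c(shape, 1L)
    if (length(shape) == 3) return(shape)
  }
  if (spec$kind == "rnn") {
    if (length(shape) == 1) shape <- c(shape, 1L)
    if (length(shape) == 2) return(shape)
  }
  abort_deepens(sprintf("bad input shape for %s CLU: (%s)", spec$kind,
                        paste(shape, collapse = ",")), "deepens_input_error")
}

# coerce user input (matrix / array / feature_table) to the engine layout and
# report its per-sample shape
clu_coerce_x <- function(spec, x) {
  if (inherits(x, "feature_table")) x <- x$values
  if (spec$kind == "mlp") {
    x <- as.matrix(x)
    list(x = x, shape = ncol(x), n = nrow(x))
  } else if (spec$kind == "cnn") {
    d <- dim(x)
    if (length(d) == 3) { dim(x) <- c(d, 1L); d <- dim(x) }
    if (length(d) != 4) {
      abort_deepens("cnn input must be an (n, h, w, c) array", "deepens_input_error")
    }
    list(x = x, shape = d[-1], n = d[1])
  } else {
    d <- dim(x)
    if (is.null(d) || length(d) == 2) {
      x <- as.matrix(x)
      dim(x) <- c(nrow(x), ncol(x), 1L)
      d <- dim(x)
    }
    if (length(d) != 3) {
      abort_deepens("rnn input must be (n, timesteps) or (n, timesteps, c)",
                    "deepens_input_error")
    }
    list(x = x, shape = d[-1], n = d[1])
  }
}

# ---- forward / backward per kind -------------------------------------------

clu_forward <- function(spec, params, X, want_cache = FALSE) {
  out_act <- if (spec$output_mode == "probability") "sigmoid" else "linear"
  if (spec$kind == "mlp") {
    L <- length(params)
    As <- vector("list", L + 1)
    As[[1]] <- X
    for (i in seq_len(L)) {
      act <- if (i < L) spec$activation else out_act
      As[[i + 1]] <- act_forward(dense_forward(As[[i]], params[[i]]), act)
    }
    pred <- As[[L + 1]][, 1]
    if (want_cache) list(pred = pred, cache = As) else list(pred = pred)
  } else if (spec$kind == "cnn") {
    B <- length(params$conv)
    cache <- list(inputs = vector("list", B), relu = vector("list", B),
                  pool = vector("list", B))
    A <- X
    for (b in seq_len(B)) {
      cache$inputs[[b]] <- A
      Z <- conv_forward(A, params$conv[[b]])
      R <- act_forward(Z, spec$activation)
      cache$relu[[b]] <- R
      pf <- maxpool_forward(R)
      if (want_cache) cache$pool[[b]] <- pf
      A <- pf$out
    }
    n <- dim(A)[1]
    flat <- A; dim(flat) <- c(n, prod(dim(A)[-1]))
    pred <- act_forward(dense_forward(flat, params$head), out_act)[, 1]
    if (want_cache) list(pred = pred, cache = cache, flat = flat, pooled_dim = dim(A))
    else list(pred = pred)
  } else {
    fw <- gru_forward(X, params$gru)
    pred <- act_forward(dense_forward(fw$ctx, params$head), out_act)[, 1]
    if (want_cache) list(pred = pred, fw = fw) else list(pred = pred)
  }
}

clu_backward <- function(spec, params, X, fwd, y) {
  dZ <- matrix(loss_output_grad(fwd$pred, y, spec$loss), ncol = 1)
  if (spec$kind == "mlp") {
    L <- length(params)
    grads <- vector("list", L)
    d <- dZ
    for (i in rev(seq_len(L))) {
      if (i < L) d <- act_backward(d, fwd$cache[[i + 1]], spec$activation)
      bk <- dense_backward(d, fwd$cache[[i]], params[[i]])
      grads[[i]] <- list(W = bk$dW, b = bk$db)
      d <- bk$dX
    }
    grads
  } else if (spec$kind == "cnn") {
    bk <- dense_backward(dZ, fwd$flat, params$head)
    grads <- list(conv = vector("list", length(params$conv)),
                  head = list(W = bk$dW, b = bk$db))
    dA <- bk$dX; dim(dA) <- fwd$pooled_dim
    for (b in rev(seq_along(params$conv))) {
      R <- fwd$cache$relu[[b]]
      dR <- maxpool_backward(dA, fwd$cache$pool[[b]], dim(R))
      dZc <- act_backward(dR, R, spec$activation)
      cb <- conv_backward(dZc, fwd$cache$inputs[[b]], params$conv[[b]])
      grads$conv[[b]] <- list(W = cb$dW, b = cb$db)
      dA <- cb$dX
    }
    grads
  } else {
    bk <- dense_backward(dZ, fwd$fw$ctx, params$head)
    ggru <- gru_backward(bk$dX, X, params$gru, fwd$fw)
    list(gru = ggru, head = list(W = bk$dW, b = bk$db))
  }
}

# strip non-trainable bookkeeping entries (cnn stores its spatial dims)
clu_trainable <- function(spec, params) {
  if (spec$kind == "cnn") params[c("conv", "head")] else params
}
clu_merge_trainable <- function(spec, params, trained) {
  if (spec$kind == "cnn") { params$conv <- trained$conv; params$head <- trained$head; params }
  else trained
}

# ---- learning-rate schedule ------------------------------------------------

#' Step-decay learning-rate schedule
#'
#' Every `period` completed epochs the learning rate is reduced by 10%
#' (`lambda <- lambda - lambda * 0.1`); between decay points it is returned
#' unchanged. After k decay points the rate is `initial * 0.9^k`.
#'
#' @param current_lr current learning rate (> 0).
#' @param epoch_index number of completed epochs (0-based).
#' @param period epochs between decays (default 50).
#' @return the (possibly decayed) learning rate.
#' @export
lr_schedule_update <- function(current_lr, epoch_index, period = 50L) {
  stopifnot(current_lr > 0, epoch_index >= 0, period >= 1)
  if (epoch_index > 0 && epoch_index %% period == 0) current_lr * 0.9 else current_lr
}

# ---- training ---------------------------------------------------------------

#' Train a CLU with checkpointing on the validation loss
#'
#' Runs mini-batch training for `spec$epochs` epochs with the step-decay
#' learning-rate schedule, evaluating the validation loss after every epoch
#' and keeping the parameters of the epoch at which it is minimal (the
#' returned model is that checkpoint, not necessarily the last epoch).
#' Fully deterministic for a fixed spec (seed) and data.
#'
#' @param clu an unfitted (or fitted) [build_clu()] object.
#' @param train,val lists with elements `x` (matrix/array, or a
#'   `feature_table`) and `y` (binary or real targets). `val` must be
#'   non-empty.
#' @return a list with `clu` (fitted) and `log` (a `training_log`
#'   data.frame: epoch, train_loss, val_loss, lr; attribute `best_epoch`).
#' @export
train_clu <- function(clu, train, val) {
  if (!inherits(clu, "clu")) abort_deepens("not a clu", "deepens_config_error")
  spec <- clu$spec
  tr <- clu_coerce_x(spec, train$x)
  va <- clu_coerce_x(spec, val$x)
  if (tr$n == 0) abort_deepens("empty training set", "deepens_input_error")
  if (va$n == 0) abort_deepens("validation set must be non-empty", "deepens_input_error")
  if (!identical(tr$shape, va$shape)) {
    abort_deepens("train and validation feature shapes differ", "deepens_input_error")
  }
  y <- as.numeric(train$y); yv <- as.numeric(val$y)
  if (length(y) != tr$n || length(yv) != va$n) {
    abort_deepens("label length does not match inputs", "deepens_input_error")
  }

  params <- clu$parameters
  if (is.null(params)) params <- clu_init_params(spec, clu_norm_shape(spec, tr$shape))

  n <- tr$n
  log_epoch <- integer(spec$epochs)
  log_train <- log_val <- log_lr <- numeric(spec$epochs)
  best_val <- Inf; best_params <- params; best_epoch <- NA_integer_

  with_rng_seed(spec$seed + 104729L, {
    lr <- spec$initial_lr
    trainable <- clu_trainable(spec, params)
    state <- opt_init(trainable)
    for (e in seq_len(spec$epochs)) {
      lr <- lr_schedule_update(lr, e - 1L, spec$lr_period)
      perm <- sample.int(n)
      starts <- seq(1, n, by = spec$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- perm[starts[bi]:min(starts[bi] + spec$batch_size - 1L, n)]
        xb <- clu_slice(spec, tr$x, idx)
        yb <- y[idx]
        fwd <- clu_forward(spec, params, xb, want_cache = TRUE)
        batch_losses[bi] <- loss_value(fwd$pred, yb, spec$loss)
        grads <- clu_backward(spec, params, xb, fwd, yb)
        if (spec$l2 > 0) grads <- add_weight_decay(grads, trainable, spec$l2)
        stepped <- opt_step(trainable, grads, state, spec$optimizer, lr)
        trainable <- stepped$params; state <- stepped$state
        params <- clu_merge_trainable(spec, params, trainable)
      }
      train_loss <- mean(batch_losses)
      val_pred <- clu_forward(spec, params, va$x)$pred
      val_loss <- loss_value(val_pred, yv, spec$loss)
      if (!is.finite(train_loss) || !is.finite(val_loss)) {
        abort_deepens(sprintf("training diverged (non-finite loss at epoch %d)", e),
                      "deepens_diverged_error")
      }
      log_epoch[e] <- e; log_train[e] <- train_loss
      log_val[e] <- val_loss; log_lr[e] <- lr
      if (val_loss < best_val) {
        best_val <- val_loss; best_params <- params; best_epoch <- e
      }
    }
  })

  log <- data.frame(epoch = log_epoch, train_loss = log_train,
                    val_loss = log_val, lr = log_lr)
  attr(log, "best_epoch") <- best_epoch
  class(log) <- c("training_log", "data.frame")
  clu$parameters <- best_params
  clu$is_fitted <- TRUE
  clu$input_shape <- tr$shape
  clu$best_val_loss <- best_val
  list(clu = clu, log = log)
}

clu_slice <- function(spec, x, idx) {
  if (spec$kind == "mlp") x[idx, , drop = FALSE]
  else if (spec$kind == "cnn") x[idx, , , , drop = FALSE]
  else x[idx, , , drop = FALSE]
}

#' Predict scores from a fitted CLU
#'
#' Returns one value per input row: a probability in \[0, 1\] for
#' `output_mode = "probability"`, an unbounded real for `"regression"`.
#'
#' @param clu a fitted CLU.
#' @param inputs matrix / array / `feature_table` matching the training shape.
#' @return numeric vector, one score per row.
#' @export
predict_proba <- function(clu, inputs) {
  if (!inherits(clu, "clu")) abort_deepens("not a clu", "deepens_config_error")
  if (!clu$is_fitted) abort_deepens("CLU is not fitted", "deepens_state_error")
  xx <- clu_coerce_x(clu$spec, inputs)
  if (!identical(as.integer(xx$shape), as.integer(clu$input_shape))) {
    abort_deepens(sprintf("input shape (%s) does not match fitted shape (%s)",
                          paste(xx$shape, collapse = ","),
                          paste(clu$input_shape, collapse = ",")),
                  "deepens_input_error")
  }
  clu_forward(clu$spec, clu$parameters, xx$x)$pred
}

# ---- serialization ----------------------------------------------------------

#' Read / write a CLU spec as YAML
#' @param spec a [clu_spec()]; `path` a file path.
#' @return `read_clu_spec` returns a `clu_spec`.
#' @export
write_clu_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_clu_spec
#' @param path file path.
#' @export
read_clu_spec <- function(path) {
  f <- yaml::read_yaml(path)
  do.call(clu_spec, f)
}

#' Export a training log as CSV (epoch, train_loss, val_loss, lr)
#' @param log a `training_log` from [train_clu()].
#' @param path file path.
#' @export
write_training_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained CLU (native R serialization)
#' @param clu a CLU; `path` a file path.
#' @export
save_clu <- function(clu, path) { saveRDS(clu, path); invisible(path) }

#' @rdname save_clu
#' @param path file path.
#' @export
load_clu <- function(path) readRDS(path)
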