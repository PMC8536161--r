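# Core learning units: spec validation, deterministic builds, the learning
# rate schedule, checkpoint-on-best-validation-loss training, and analytic
# gradients verified against central differences.

test_that("spec validation rejects bad configurations", {
  expect_error(clu_spec("mlp", integer(0)), class = "deepens_config_error")
  expect_error(clu_spec("boost"), class = "deepens_config_error")
  expect_error(clu_spec("mlp", c(8, 2)), class = "deepens_config_error")
  expect_error(clu_spec("mlp", c(8, 1), activation = "softplus"),
               class = "deepens_config_error")
  expect_error(clu_spec("mlp", c(8, 1), output_mode = "probability",
                        loss = "mean_squared_error"),
               class = "deepens_config_error")
  expect_error(clu_spec("mlp", c(8, 1), output_mode = "regression",
                        loss = "binary_cross_entropy"),
               class = "deepens_config_error")
  expect_error(clu_spec("mlp", c(8, 1), optimizer = "rmsprop"),
               class = "deepens_config_error")
  expect_error(clu_spec("mlp", c(8, 1), initial_lr = 0),
               class = "deepens_config_error")
})

test_that("loss/optimizer defaults follow output mode", {
  cls <- clu_spec("mlp", c(8, 1))
  expect_equal(cls$loss, "binary_cross_entropy")
  expect_equal(cls$optimizer, "adam")
  reg <- clu_spec("mlp", c(8, 1), output_mode = "regression")
  expect_equal(reg$loss, "mean_squared_error")
  expect_equal(reg$optimizer, "sgd")
})

test_that("building the same spec twice yields identical parameters", {
  spec <- clu_spec("mlp", c(16, 8, 1), seed = 7, input_shape = 5)
  expect_identical(build_clu(spec)$parameters, build_clu(spec)$parameters)
  spec_cnn <- clu_spec("cnn", c(4, 1), seed = 3, input_shape = c(8, 8, 1))
  expect_identical(build_clu(spec_cnn)$parameters, build_clu(spec_cnn)$parameters)
})

test_that("learning-rate schedule decays 10% at period multiples only", {
  expect_equal(lr_schedule_update(0.1, 50), 0.09)
  expect_equal(lr_schedule_update(0.1, 49), 0.1)
  expect_equal(lr_schedule_update(0.1, 0), 0.1)
  expect_equal(lr_schedule_update(0.05, 6, period = 3), 0.045)
  lr <- 0.1
  for (e in 1:150) lr <- lr_schedule_update(lr, e)
  expect_equal(lr, 0.0729)
})

test_that("learning rate follows the closed form initial * 0.9^k", {
  for (k in 1:10) {
    lr <- 0.2
    for (e in seq_len(k * 50)) lr <- lr_schedule_update(lr, e)
    expect_equal(lr, 0.2 * 0.9^k, tolerance = 1e-12)
  }
})

test_that("logged learning rate is non-increasing and matches the schedule", {
  d <- separable_data(60, seed = 11)
  spec <- clu_spec("mlp", c(4, 1), epochs = 12, lr_period = 5L,
                   initial_lr = 0.1, seed = 2)
  log <- train_clu(build_clu(spec), d, list(x = d$x[1:10, ], y = d$y[1:10]))$log
  expect_true(all(diff(log$lr) <= 0))
  expect_equal(log$lr[1], 0.1)
  expect_equal(log$lr[6], 0.09)   # first decay after 5 completed epochs
  expect_equal(log$lr[11], 0.081)
})

test_that("probability CLUs of every kind score random inputs inside [0,1]", {
  set.seed(99)
  d <- separable_data(40, seed = 5)
  mlp <- train_clu(build_clu(clu_spec("mlp", c(4, 1), epochs = 3, seed = 1)),
                   d, d)$clu
  expect_true(all(predict_proba(mlp, matrix(rnorm(200), 100)) >= 0 &
                  predict_proba(mlp, matrix(rnorm(200), 100)) <= 1))

  xr <- array(runif(10 * 12 * 2), c(10, 12, 2))
  rnn <- train_clu(build_clu(clu_spec("rnn", c(4, 1), epochs = 2, seed = 1)),
                   list(x = xr, y = rep_len(0:1, 10)),
                   list(x = xr, y = rep_len(0:1, 10)))$clu
  p <- predict_proba(rnn, array(rnorm(100 * 12 * 2), c(100, 12, 2)))
  expect_length(p, 100)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("training separates linearly separable data perfectly", {
  d <- separable_data(200, seed = 3)
  spec <- clu_spec("mlp", c(8, 1), epochs = 100, initial_lr = 0.05, seed = 4)
  fit <- train_clu(build_clu(spec), d, list(x = d$x[1:40, ], y = d$y[1:40]))
  acc <- mean((predict_proba(fit$clu, d$x) >= 0.5) == d$y)
  expect_equal(acc, 1.0)
})

test_that("checkpointing restores the parameters of the best epoch", {
  d <- separable_data(120, seed = 8)
  val <- list(x = d$x[1:30, ], y = d$y[1:30])
  spec <- clu_spec("mlp", c(6, 1), epochs = 40, initial_lr = 0.05, seed = 6)
  fit <- train_clu(build_clu(spec), d, val)
  best <- attr(fit$log, "best_epoch")
  expect_equal(fit$log$val_loss[best], min(fit$log$val_loss))
  # reported checkpointed loss equals recomputed loss of the returned model
  p <- predict_proba(fit$clu, val$x)
  recomputed <- -mean(val$y * log(pmin(pmax(p, 1e-12), 1 - 1e-12)) +
                      (1 - val$y) * log(1 - pmin(pmax(p, 1e-12), 1 - 1e-12)))
  expect_equal(recomputed, min(fit$log$val_loss), tolerance = 1e-9)
})

test_that("training is bitwise deterministic given spec and data", {
  d <- separable_data(80, seed = 10)
  val <- list(x = d$x[1:16, ], y = d$y[1:16])
  spec <- clu_spec("mlp", c(5, 1), epochs = 10, seed = 12)
  f1 <- train_clu(build_clu(spec), d, val)
  f2 <- train_clu(build_clu(spec), d, val)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$clu$parameters, f2$clu$parameters)
  expect_identical(predict_proba(f1$clu, d$x), predict_proba(f2$clu, d$x))
})

test_that("duplicated rows predict identically and shape errors are caught", {
  clu <- fitted_mlp(seed = 2)
  x <- matrix(rnorm(10), 5)
  p <- predict_proba(clu, rbind(x, x[1, , drop = FALSE]))
  expect_equal(p[6], p[1], tolerance = 1e-12)
  # same batch scored twice is bitwise identical
  expect_identical(predict_proba(clu, x), predict_proba(clu, x))
  expect_error(predict_proba(clu, matrix(0, 2, 7)), class = "deepens_input_error")
  expect_error(predict_proba(build_clu(clu$spec), x), class = "deepens_state_error")
})

test_that("empty training or validation sets are rejected", {
  d <- separable_data(30, seed = 1)
  spec <- clu_spec("mlp", c(4, 1), epochs = 2, seed = 1)
  expect_error(train_clu(build_clu(spec),
                         list(x = d$x[0, , drop = FALSE], y = integer(0)), d),
               class = "deepens_input_error")
  expect_error(train_clu(build_clu(spec), d,
                         list(x = d$x[0, , drop = FALSE], y = integer(0))),
               class = "deepens_input_error")
  expect_error(train_clu(build_clu(spec), d,
                         list(x = matrix(0, 3, 5), y = c(0, 1, 0))),
               class = "deepens_input_error")
})

test_that("divergent training raises a dedicated error", {
  d <- separable_data(40, seed = 2)
  d$x <- d$x * 1e4
  spec <- clu_spec("mlp", c(4, 1), output_mode = "regression",
                   epochs = 10, initial_lr = 1e6, seed = 1)
  expect_error(train_clu(build_clu(spec), list(x = d$x, y = d$x[, 1] * 1e4),
                         list(x = d$x, y = d$x[, 1] * 1e4)),
               class = "deepens_diverged_error")
})

test_that("analytic gradients match central differences for all CLU kinds", {
  set.seed(21)
  cases <- list(
    list(spec = clu_spec("mlp", c(5, 3, 1), seed = 3),
         x = matrix(rnorm(24), 6), shape = 4L),
    list(spec = clu_spec("mlp", c(4, 1), output_mode = "regression", seed = 5),
         x = matrix(rnorm(24), 6), shape = 4L),
    list(spec = clu_spec("cnn", c(3, 4, 1), seed = 7),
         x = array(rnorm(5 * 8 * 8), c(5, 8, 8, 1)), shape = c(8L, 8L, 1L)),
    list(spec = clu_spec("rnn", c(4, 1), seed = 11),
         x = array(rnorm(5 * 6 * 2), c(5, 6, 2)), shape = c(6L, 2L)))
  for (cs in cases) {
    y <- if (cs$spec$output_mode == "regression") rnorm(dim(cs$x)[1])
         else rep_len(0:1, dim(cs$x)[1])
    params <- deepens:::clu_init_params(cs$spec, cs$shape)
    fwd <- deepens:::clu_forward(cs$spec, params, cs$x, want_cache = TRUE)
    g <- deepens:::clu_backward(cs$spec, params, cs$x, fwd, y)
    trainable <- deepens:::clu_trainable(cs$spec, params)
    ng <- numeric_gradient(function(p) {
      full <- deepens:::clu_merge_trainable(cs$spec, params, p)
      deepens:::loss_value(deepens:::clu_forward(cs$spec, full, cs$x)$pred,
                           y, cs$spec$loss)
    }, trainable)
    expect_lt(max(abs(unlist(g) - unlist(ng))), 1e-6)
  }
})

test_that("L2 weight decay shrinks weight matrices but not the fit contract", {
  d <- separable_data(100, seed = 19)
  val <- list(x = d$x[1:20, ], y = d$y[1:20])
  w_norm <- function(l2) {
    spec <- clu_spec("mlp", c(6, 1), epochs = 15, initial_lr = 0.05,
                     seed = 3, l2 = l2)
    fit <- train_clu(build_clu(spec), d, val)$clu
    sum(vapply(fit$parameters, function(p) sum(abs(p$W)), 0))
  }
  expect_lt(w_norm(0.5), w_norm(0))
  expect_error(clu_spec("mlp", c(6, 1), l2 = -1))
})

test_that("spec YAML and training-log CSV round-trip", {
  spec <- clu_spec("rnn", c(8, 1), epochs = 7, seed = 42)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_clu_spec(spec, f)
  expect_equal(read_clu_spec(f), spec)
  d <- separable_data(40, seed = 4)
  log <- train_clu(build_clu(clu_spec("mlp", c(3, 1), epochs = 4, seed = 1)),
                   d, d)$log
  csv <- withr::local_tempfile(fileext = ".csv")
  write_training_log(log, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$val_loss, log$val_loss)
  expect_named(back, c("epoch", "train_loss", "val_loss", "lr"))
})
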