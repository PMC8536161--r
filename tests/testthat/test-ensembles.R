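# The three ensemble meta-algorithms: aggregation exactness, boosting
# recursion, stacking metadata, determinism, and learning performance on
# planted-signal data.

test_that("DAL score equals the explicit loop-and-average of member scores", {
  members <- lapply(1:3, fitted_mlp)
  model <- new_dal_model(members)
  x <- separable_data(25, seed = 77)$x
  pred <- predict_dal(model, x)
  acc <- NULL
  for (m in members) {
    p <- predict_proba(m, x)
    acc <- if (is.null(acc)) p else acc + p
  }
  expect_identical(pred$scores, acc / 3)
  expect_equal(pred$classes, as.integer(pred$scores >= 0.5))
})

test_that("an ensemble of identical members equals the member", {
  m <- fitted_mlp(seed = 4)
  x <- separable_data(10, seed = 1)$x
  same <- new_dal_model(list(m, m, m))
  expect_equal(predict_dal(same, x)$scores, predict_proba(m, x))
})

test_that("a one-member DAL on the full training set equals the single CLU", {
  d <- separable_data(100, seed = 14)
  val <- list(x = d$x[1:20, ], y = d$y[1:20])
  spec <- clu_spec("mlp", c(5, 1), epochs = 15, seed = 9)
  dal <- fit_dal(d, val, spec, n_members = 1, subset_mode = "full")
  single <- train_clu(build_clu(spec), d, val)$clu
  x <- separable_data(30, seed = 15)$x
  expect_identical(predict_dal(dal, x)$scores, predict_proba(single, x))
})

test_that("DAL fitting is deterministic and members differ by subset/seed", {
  d <- separable_data(120, seed = 16)
  val <- list(x = d$x[1:24, ], y = d$y[1:24])
  spec <- clu_spec("mlp", c(4, 1), epochs = 8, batch_size = 16, seed = 3)
  m1 <- fit_dal(d, val, spec, n_members = 3)
  m2 <- fit_dal(d, val, spec, n_members = 3)
  x <- separable_data(20, seed = 17)$x
  expect_identical(predict_dal(m1, x)$scores, predict_dal(m2, x)$scores)
  expect_false(identical(m1$members[[1]]$parameters, m1$members[[2]]$parameters))
  expect_false(identical(m1$subset_assignments[[1]], m1$subset_assignments[[2]]))
})

test_that("mode aggregation breaks even ties toward the positive class", {
  members <- lapply(1:2, fitted_mlp)
  model <- new_dal_model(members, aggregator = "mode")
  x <- separable_data(12, seed = 18)$x
  pred <- predict_dal(model, x)
  votes <- (predict_proba(members[[1]], x) >= 0.5) +
           (predict_proba(members[[2]], x) >= 0.5)
  expect_equal(pred$classes, as.integer(votes / 2 >= 0.5))
  expect_true(all(pred$classes[votes == 1] == 1L))  # 1-1 split -> positive
})

test_that("DAL reaches >= 0.95 accuracy on planted-signal tabular data", {
  ft <- gen_statistical(statistical_gen_spec(n_samples = 500, effect_size = 3,
                                             missing_rate = 0, seed = 21))
  fold <- split_dataset(500, split_spec(seed = 21))[[1]]
  spec <- clu_spec("mlp", c(8, 1), epochs = 25, initial_lr = 0.02, seed = 5)
  sets <- lapply(fold, function(i) list(x = ft$values[i, ], y = ft$labels[i]))
  dal <- fit_dal(sets$train, sets$val, spec, n_members = 5)
  acc <- mean(predict_dal(dal, sets$test$x)$classes == sets$test$y)
  expect_gte(acc, 0.95)
})

test_that("ensemble-score variance at a fixed point is below member variance", {
  d <- separable_data(100, seed = 30, margin = 0.3)
  val <- list(x = d$x[1:20, ], y = d$y[1:20])
  spec <- clu_spec("mlp", c(4, 1), epochs = 6, batch_size = 16, seed = 1)
  x0 <- matrix(c(0.1, -0.2), 1)
  ens <- numeric(20); mem <- matrix(0, 20, 3)
  for (r in 1:20) {
    m <- fit_dal(d, val, spec, n_members = 3, seed = 100 + r)
    ens[r] <- predict_dal(m, x0)$scores
    mem[r, ] <- vapply(m$members, function(cl) predict_proba(cl, x0), 0)
  }
  expect_lte(var(ens), mean(apply(mem, 2, var)) * 1.05)
})

test_that("GDLB base prediction is the training label mean", {
  zero_fitter <- function(x, resid, i) function(newx) rep(0, NROW(newx))
  d <- list(x = matrix(rnorm(8), 4), y = c(0, 0, 1, 1))
  m <- fit_gdlb(d, d, NULL, n_boosters = 3, lr_policy = 0.5,
                booster_fitter = zero_fitter)
  expect_equal(m$p_base, 0.5)
  # zero boosters leave every prediction at P_base
  p <- predict_gdlb(m, matrix(rnorm(10), 5))
  expect_equal(p$scores, rep(0.5, 5))
  expect_equal(m$staged_mse, rep(0.25, 4))
})

test_that("GDLB raw score follows P_base + sum lambda_i * O_i", {
  const_fitter <- function(v) function(x, resid, i) function(newx) rep(v, NROW(newx))
  d <- list(x = matrix(rnorm(8), 4), y = c(0, 0, 1, 1))
  m <- fit_gdlb(d, d, NULL, n_boosters = 1, lr_policy = 0.5,
                booster_fitter = const_fitter(0.4))
  p <- predict_gdlb(m, matrix(0, 3, 2))
  expect_equal(p$raw, rep(0.5 + 0.5 * 0.4, 3))
})

test_that("an exact-fit booster with lambda = 1 zeroes the training residual", {
  d <- list(x = matrix(rnorm(20), 10), y = rep_len(0:1, 10))
  exact_fitter <- function(x, resid, i) {
    n <- NROW(x); r <- resid
    function(newx) if (NROW(newx) == n) r else rep(0, NROW(newx))
  }
  m <- fit_gdlb(d, list(x = matrix(rnorm(6), 3), y = c(0, 1, 0)), NULL,
                n_boosters = 1, lr_policy = 1, booster_fitter = exact_fitter)
  expect_equal(m$staged_mse[2], 0)
})

test_that("constant-fit boosters give non-increasing staged training MSE", {
  set.seed(41)
  d <- list(x = matrix(rnorm(40), 20), y = rbinom(20, 1, 0.3))
  const_fitter <- function(x, resid, i) {
    m <- mean(resid); function(newx) rep(m, NROW(newx))
  }
  fit <- fit_gdlb(d, d, NULL, n_boosters = 10, lr_policy = 0.4,
                  booster_fitter = const_fitter)
  expect_true(all(diff(fit$staged_mse) <= 1e-12))
})

test_that("uniform lambda policy draws per-booster rates in (0,1), seeded", {
  d <- separable_data(80, seed = 42)
  val <- list(x = d$x[1:16, ], y = d$y[1:16])
  spec <- clu_spec("mlp", c(3, 1), output_mode = "regression", epochs = 4,
                   initial_lr = 0.01, seed = 2)
  m1 <- fit_gdlb(d, val, spec, n_boosters = 4)
  m2 <- fit_gdlb(d, val, spec, n_boosters = 4)
  expect_identical(m1$lambdas, m2$lambdas)
  expect_true(all(m1$lambdas > 0 & m1$lambdas < 1))
  expect_gt(length(unique(m1$lambdas)), 1)
  expect_error(fit_gdlb(d, val, spec, n_boosters = 0),
               class = "deepens_config_error")
  expect_error(fit_gdlb(d, val, clu_spec("mlp", c(3, 1)), n_boosters = 2),
               class = "deepens_config_error")
})

test_that("GDLB learns planted-signal data with neural boosters", {
  ft <- gen_statistical(statistical_gen_spec(n_samples = 400, effect_size = 3,
                                             missing_rate = 0, seed = 43))
  fold <- split_dataset(400, split_spec(seed = 43))[[1]]
  sets <- lapply(fold, function(i) list(x = ft$values[i, ], y = ft$labels[i]))
  spec <- clu_spec("mlp", c(8, 1), output_mode = "regression", epochs = 15,
                   initial_lr = 0.02, seed = 3)
  m <- fit_gdlb(sets$train, sets$val, spec, n_boosters = 5)
  expect_lt(m$staged_mse[length(m$staged_mse)], m$staged_mse[1])
  acc <- mean(predict_gdlb(m, sets$test$x)$classes == sets$test$y)
  expect_gte(acc, 0.9)
})

test_that("metadata columns equal per-member scores in member order", {
  members <- lapply(1:3, fitted_mlp)
  x <- separable_data(10, seed = 51)$x
  meta <- build_metadata(members, x)
  expect_equal(dim(meta), c(10L, 3L))
  for (i in 1:3) expect_identical(meta[, i], predict_proba(members[[i]], x))
  # duplicated input row -> duplicated metadata row
  meta2 <- build_metadata(members, rbind(x, x[1, , drop = FALSE]))
  expect_identical(meta2[11, ], meta2[1, ])
  expect_error(build_metadata(list(), x), class = "deepens_config_error")
})

test_that("a column-mean meta-learner reduces DeSGEL to DAL bitwise", {
  members <- lapply(1:4, fitted_mlp)
  mean_meta <- function(meta) {
    acc <- meta[, 1]
    for (i in 2:ncol(meta)) acc <- acc + meta[, i]
    acc / ncol(meta)
  }
  desgel <- new_desgel_model(members, mean_meta)
  dal <- new_dal_model(members)
  x <- separable_data(30, seed = 52)$x
  expect_identical(predict_desgel(desgel, x)$scores, predict_dal(dal, x)$scores)
})

test_that("a single member with an identity meta-learner equals the member", {
  m <- fitted_mlp(seed = 6)
  desgel <- new_desgel_model(list(m), function(meta) meta[, 1])
  x <- separable_data(15, seed = 53)$x
  expect_identical(predict_desgel(desgel, x)$scores, predict_proba(m, x))
})

test_that("DeSGEL trains level 1 on held-out metadata and learns the signal", {
  ft <- gen_statistical(statistical_gen_spec(n_samples = 500, effect_size = 3,
                                             missing_rate = 0, seed = 54))
  fold <- split_dataset(500, split_spec(seed = 54))[[1]]
  sets <- lapply(fold, function(i) list(x = ft$values[i, ], y = ft$labels[i]))
  spec <- clu_spec("mlp", c(8, 1), epochs = 20, initial_lr = 0.02, seed = 4)
  m <- fit_desgel(sets$train, sets$val, spec, n_members = 5)
  pred <- predict_desgel(m, sets$test$x)
  expect_true(all(pred$scores >= 0 & pred$scores <= 1))
  expect_gte(mean(pred$classes == sets$test$y), 0.95)
  # stacked validation accuracy is not far below the best member's
  val_acc <- mean(predict_desgel(m, sets$val$x)$classes == sets$val$y)
  member_acc <- vapply(m$level0, function(cl) {
    mean((predict_proba(cl, sets$val$x) >= 0.5) == sets$val$y)
  }, 0)
  expect_gte(val_acc, max(member_acc) - 0.02)
})

test_that("ensembles are reproducible from (config, seed) and serialisable", {
  d <- separable_data(100, seed = 55)
  val <- list(x = d$x[1:20, ], y = d$y[1:20])
  spec <- clu_spec("mlp", c(4, 1), epochs = 6, seed = 8)
  m1 <- fit_desgel(d, val, spec, n_members = 2)
  m2 <- fit_desgel(d, val, spec, n_members = 2)
  x <- separable_data(10, seed = 56)$x
  expect_identical(predict_desgel(m1, x)$scores, predict_desgel(m2, x)$scores)
  dir <- withr::local_tempdir()
  save_ensemble(m1, dir)
  back <- load_ensemble(dir)
  expect_identical(predict_desgel(back, x)$scores, predict_desgel(m1, x)$scores)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_predictions(predict_desgel(m1, x), f)
  expect_equal(nrow(utils::read.csv(f)), 10)
})
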