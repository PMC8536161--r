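# Phase-1 preprocessing: imputation, scaling, splitting, feature ranking,
# windows, resizing — contracts, idempotence and leakage freedom.

test_that("feature-mean imputation fills with the column mean of observed values", {
  ft <- feature_table(cbind(a = c(1, NA, 3), b = c(4, 5, 6)), c(0, 1, 0))
  out <- impute_feature_mean(ft)
  expect_equal(unname(out$values[2, "a"]), 2)
  expect_equal(out$values[, "b"], c(4, 5, 6), ignore_attr = TRUE)
  expect_false(any(out$missing_mask))
})

test_that("imputation is the identity on complete tables and idempotent", {
  ft <- feature_table(matrix(rnorm(20), 5), rep_len(0:1, 5))
  expect_equal(impute_feature_mean(ft), ft)
  ft2 <- feature_table(cbind(c(1, NA, 3), c(NA, 5, 6)), c(0, 1, 0))
  once <- impute_feature_mean(ft2)
  expect_equal(impute_feature_mean(once), once)
})

test_that("an all-missing feature is reported by name", {
  ft <- feature_table(cbind(ok = 1:3, bad = rep(NA_real_, 3)), c(0, 1, 0))
  expect_error(impute_feature_mean(ft), "bad", class = "deepens_input_error")
})

test_that("time-of-day imputation averages the same minute across days", {
  # minute 600 observed on days 1 and 3 (10, 20), missing on day 2
  miss_at <- 1440 + 601
  p <- make_recording(day_values = c(1, 1, 1))
  p$values[601] <- 10; p$values[2 * 1440 + 601] <- 20; p$values[miss_at] <- NA
  rec <- recording_set(list(p))
  out <- impute_participant_time_mean(rec)
  expect_equal(out$participants[[1]]$values[miss_at], 15)
  # untouched elsewhere
  expect_equal(out$participants[[1]]$values[1], 1)
  expect_false(any(out$participants[[1]]$missing_mask[miss_at]))
})

test_that("time-of-day imputation is identity without gaps, idempotent, and
           falls back to the participant mean for always-missing minutes", {
  rec <- recording_set(list(make_recording(day_values = c(2, 4, 6))))
  expect_equal(impute_participant_time_mean(rec)$participants[[1]]$values,
               rec$participants[[1]]$values)
  # minute 100 missing on every day -> participant grand mean of the rest
  idx <- 100 + 1440 * (0:2)
  p <- make_recording(day_values = c(2, 4, 6), missing_at = idx)
  rec2 <- recording_set(list(p))
  out <- impute_participant_time_mean(rec2)
  expect_equal(out$participants[[1]]$values[idx],
               rep(mean(p$values, na.rm = TRUE), 3))
  expect_equal(impute_participant_time_mean(out), out)
  expect_error(impute_participant_time_mean(
    recording_set(list(make_recording(day_values = NA_real_)))),
    class = "deepens_state_error")
})

test_that("standard scaler centres and scales exactly as fitted on train", {
  tr <- feature_table(matrix(c(0, 2), 2, 1), c(0, 1), "x")
  sc <- fit_standard_scaler(tr)
  expect_equal(sc$mu, c(x = 1))
  expect_equal(sc$sigma, c(x = 1))   # population sd of {0, 2}
  expect_equal(apply_standard_scaler(sc, tr)$values[, 1], c(-1, 1),
               ignore_attr = TRUE)
  te <- feature_table(matrix(4, 1, 1), 1, "x")
  expect_equal(unname(apply_standard_scaler(sc, te)$values[1, 1]), 3)
})

test_that("scaled training features have mean 0 sd 1; round-trip recovers input", {
  ft <- feature_table(matrix(rnorm(200, 5, 3), 40), rep_len(0:1, 40))
  sc <- fit_standard_scaler(ft)
  z <- apply_standard_scaler(sc, ft)
  expect_lt(max(abs(colMeans(z$values))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(sweep(z$values, 2, colMeans(z$values))^2)) - 1)),
            1e-9)
  back <- invert_standard_scaler(sc, z)
  expect_lt(max(abs(back$values - ft$values)), 1e-9)
})

test_that("constant features scale to zero with sigma coerced to 1", {
  ft <- feature_table(cbind(k = c(5, 5, 5), v = c(1, 2, 3)), c(0, 1, 0))
  expect_warning(sc <- fit_standard_scaler(ft), "zero-variance")
  expect_equal(sc$sigma[["k"]], 1)
  expect_equal(apply_standard_scaler(sc, ft)$values[, "k"], c(0, 0, 0),
               ignore_attr = TRUE)
})

test_that("splits are sized by largest remainder, disjoint and exhaustive", {
  folds <- split_dataset(100, split_spec(seed = 1))
  expect_length(folds[[1]]$train, 80)
  expect_length(folds[[1]]$val, 4)
  expect_length(folds[[1]]$test, 16)
  folds25 <- split_dataset(25, split_spec(seed = 2))
  expect_equal(vapply(folds25[[1]], length, 0L),
               c(train = 20L, val = 1L, test = 4L))
  f <- folds[[3]]
  expect_equal(sort(c(f$train, f$val, f$test)), 1:100)
})

test_that("test partition is fixed across folds, train/val re-drawn, seeded", {
  folds <- split_dataset(60, split_spec(folds = 5, seed = 9))
  tests <- lapply(folds, `[[`, "test")
  expect_true(all(vapply(tests, identical, TRUE, tests[[1]])))
  expect_false(identical(folds[[1]]$val, folds[[2]]$val))
  expect_identical(split_dataset(60, split_spec(folds = 5, seed = 9)), folds)
  expect_error(split_spec(c(0.5, 0.2, 0.2)), class = "deepens_config_error")
  expect_error(split_dataset(5, split_spec()), class = "deepens_input_error")
})

test_that("random-forest ranking puts a label-determining feature first", {
  set.seed(31)
  n <- 300
  y <- rep_len(0:1, n)
  v <- cbind(det = y + rnorm(n, sd = 0.05), matrix(rnorm(3 * n), n))
  ft <- feature_table(v, y, c("det", "n1", "n2", "n3"))
  rk <- rank_features_rf(ft, seed = 4)
  expect_equal(rk$feature[1], "det")
  expect_equal(sum(rk$importance), 1, tolerance = 1e-9)
  expect_true(all(diff(rk$importance) <= 0))
})

test_that("exchangeable noise features receive similar importance", {
  set.seed(32)
  n <- 1000
  y <- rep_len(0:1, n)
  ft <- feature_table(cbind(s = y + rnorm(n), a = rnorm(n), b = rnorm(n)),
                      y, c("s", "a", "b"))
  rk <- rank_features_rf(ft, seed = 7)
  noise <- rk$importance[match(c("a", "b"), rk$feature)]
  expect_lt(abs(diff(noise)), 0.1)
})

test_that("moving windows: counts, length and labels", {
  rec <- recording_set(list(make_recording("a", 1L, rep(1, 7)),
                            make_recording("b", 0L, rep(2, 13)),
                            make_recording("c", 1L, rep(3, 6))))
  expect_message(ws <- generate_windows(rec), "c: only 6")
  expect_equal(ncol(ws$values), 10080)
  counts <- table(ws$meta$participant_id)
  expect_equal(as.integer(counts[c("a", "b")]), c(1L, 7L))
  expect_false("c" %in% ws$meta$participant_id)
  expect_equal(unique(ws$meta$label[ws$meta$participant_id == "b"]), 0L)
  # consecutive windows of one participant start one day apart
  expect_equal(diff(ws$meta$start_day[ws$meta$participant_id == "b"]),
               rep(1L, 6))
})

test_that("daily-profile reduction averages the 7 values per minute-of-day", {
  p <- make_recording(day_values = 1:7)
  ws <- generate_windows(recording_set(list(p)), daily_profile = TRUE)
  expect_equal(dim(ws$values), c(1L, 1440L))
  expect_equal(unique(as.numeric(ws$values)), mean(1:7))
})

test_that("resizing standardises shape, preserves constants, skips identity", {
  st <- image_stack(list(matrix(0.4, 40, 30), matrix(runif(400), 20, 20)),
                    c(0, 1))
  out <- resize_images(st, c(20, 20, 1))
  expect_true(all(vapply(out$images, function(im) all(dim(im) == c(20, 20, 1)),
                         TRUE)))
  expect_equal(unique(as.numeric(out$images[[1]])), 0.4)
  expect_equal(out$images[[2]][, , 1], st$images[[2]][, , 1])  # identity resize
  rng <- range(unlist(out$images))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  expect_error(resize_images(image_stack(list(array(0, c(0, 30, 1))), 0),
                             c(20, 20, 1)), class = "deepens_input_error")
  expect_error(resize_images(st, c(0, 20, 1)), class = "deepens_config_error")
})

test_that("fitted preprocessing depends only on the training partition", {
  ft <- gen_statistical(statistical_gen_spec(n_samples = 60, missing_rate = 0,
                                             seed = 5))
  fold <- split_dataset(60, split_spec(seed = 5))[[1]]
  perturb <- ft
  perturb$values[fold$test, ] <- perturb$values[fold$test, ] + 100
  sc1 <- fit_standard_scaler(ft_rows(ft, fold$train))
  sc2 <- fit_standard_scaler(ft_rows(perturb, fold$train))
  expect_identical(sc1, sc2)
  rk1 <- rank_features_rf(ft_rows(ft, fold$train), seed = 2)
  rk2 <- rank_features_rf(ft_rows(perturb, fold$train), seed = 2)
  expect_identical(rk1, rk2)
})

test_that("feature-table CSV and recording CSV round-trip including missing", {
  ft <- feature_table(cbind(a = c(1, NA), b = c(3.5, 4)), c(0, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, f)
  back <- read_feature_table(f)
  expect_equal(back$values, ft$values)
  expect_equal(back$labels, ft$labels)
  rec <- recording_set(list(make_recording("p1", 1L, c(1, 2), missing_at = 7)))
  rf <- withr::local_tempfile(fileext = ".csv")
  write_recording_set(rec, rf)
  back2 <- read_recording_set(rf)
  expect_equal(back2$participants[[1]]$values, rec$participants[[1]]$values)
  expect_equal(back2$participants[[1]]$label, 1L)
})
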