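# Phase-1 preprocessing: imputation, standard scaling fitted on the training
# partition only, leakage-free splitting, random-forest feature ranking,
# image resizing, and moving-window sample generation.

#' Impute missing tabular entries with the per-feature mean
#'
#' Each missing entry is replaced by the mean of the originally non-missing
#' entries of the same feature; non-missing entries are untouched.
#'
#' @param table a [feature_table()]; every feature needs at least one
#'   non-missing value.
#' @return an imputed `feature_table` (no missing values).
#' @export
impute_feature_mean <- function(table) {
  v <- table$values
  all_missing <- colSums(!is.na(v)) == 0
  if (any(all_missing)) {
    abort_deepens(paste0("feature(s) entirely missing: ",
                         paste(table$feature_names[all_missing], collapse = ", ")),
                  "deepens_input_error")
  }
  mu <- colMeans(v, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- mu[idx[, 2]]
  feature_table(v, table$labels, table$feature_names)
}

#' Impute missing minutes with the participant's time-of-day mean
#'
#' A missing value at minute-of-day m is replaced by the mean of the same
#' participant's non-missing values at minute m across all recorded days.
#' If a minute-of-day is missing on every day, the participant's overall
#' mean is used as a within-participant fallback.
#'
#' @param recordings a [recording_set()].
#' @return an imputed `recording_set` (no missing values).
#' @export
impute_participant_time_mean <- function(recordings) {
  parts <- lapply(recordings$participants, function(p) {
    v <- p$values
    if (all(is.na(v))) {
      abort_deepens(sprintf("participant %s: series entirely missing", p$id),
                    "deepens_state_error")
    }
    m <- matrix(v, nrow = MINUTES_PER_DAY)     # minute-of-day x day
    tod_mean <- rowMeans(m, na.rm = TRUE)
    tod_mean[is.nan(tod_mean)] <- mean(v, na.rm = TRUE)
    na_at <- which(is.na(v))
    if (length(na_at)) v[na_at] <- tod_mean[((na_at - 1L) %% MINUTES_PER_DAY) + 1L]
    list(id = p$id, label = p$label, values = v)
  })
  recording_set(parts)
}

# ---- standard scaling -------------------------------------------------------

#' Fit / apply / invert the standard scaler
#'
#' `fit_standard_scaler` computes the per-feature mean and (population)
#' standard deviation on the training table only; `apply_standard_scaler`
#' centres and scales any table with those parameters
#' (`x_scaled = (x - mu) / sigma`); `invert_standard_scaler` undoes it.
#' Zero-variance features get `sigma = 1` (with a warning) so scaling is
#' always defined.
#'
#' @param train an imputed training `feature_table`.
#' @return `scaler_params` with fields `mu` and `sigma`.
#' @export
fit_standard_scaler <- function(train) {
  v <- train$values
  if (any(is.na(v))) {
    abort_deepens("scaler requires an imputed (complete) table", "deepens_input_error")
  }
  mu <- colMeans(v)
  sigma <- sqrt(colMeans(sweep(v, 2, mu)^2))
  if (any(sigma == 0)) {
    warning("zero-variance feature(s): sigma set to 1 for ",
            paste(train$feature_names[sigma == 0], collapse = ", "))
    sigma[sigma == 0] <- 1
  }
  structure(list(mu = mu, sigma = sigma), class = "scaler_params")
}

#' @rdname fit_standard_scaler
#' @param params a `scaler_params`.
#' @param table a `feature_table` to transform.
#' @export
apply_standard_scaler <- function(params, table) {
  v <- sweep(sweep(table$values, 2, params$mu), 2, params$sigma, "/")
  feature_table(v, table$labels, table$feature_names)
}

#' @rdname fit_standard_scaler
#' @export
invert_standard_scaler <- function(params, table) {
  v <- sweep(sweep(table$values, 2, params$sigma, "*"), 2, params$mu, "+")
  feature_table(v, table$labels, table$feature_names)
}

# ---- splitting --------------------------------------------------------------

#' Describe a train/validation/test split
#'
#' The test partition is drawn once and held fixed; the remaining samples
#' are re-split into train/validation once per fold. Partition sizes follow
#' largest-remainder apportionment of the proportions (ties broken
#' train, validation, test).
#'
#' @param proportions train/val/test proportions summing to 1
#'   (default `c(0.80, 0.04, 0.16)`).
#' @param folds number of train/validation re-draws (default 10).
#' @param seed RNG seed.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(proportions = c(train = 0.80, val = 0.04, test = 0.16),
                       folds = 10L, seed = 1L) {
  if (length(proportions) != 3 || abs(sum(proportions) - 1) > 1e-9) {
    abort_deepens("proportions must be three values summing to 1",
                  "deepens_config_error")
  }
  structure(list(proportions = unname(proportions), folds = as.integer(folds),
                 seed = as.integer(seed)), class = "split_spec")
}

# largest-remainder apportionment of n into parts with given proportions
apportion <- function(n, proportions) {
  exact <- n * proportions
  base <- floor(exact)
  rem <- round(n - sum(base))
  if (rem > 0) {
    frac <- exact - base
    # ties broken by partition order (train, val, test)
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Split samples into train/validation/test folds
#'
#' @param data an integer sample count, or a `feature_table`, `window_set`
#'   or `image_stack`.
#' @param spec a [split_spec()].
#' @return list of folds; each fold has integer index vectors `train`,
#'   `val`, `test` (the `test` indices identical across folds).
#' @export
split_dataset <- function(data, spec = split_spec()) {
  n <- n_samples(data)
  sizes <- apportion(n, spec$proportions)
  if (any(sizes == 0)) {
    abort_deepens(sprintf("n = %d too small: a partition would be empty", n),
                  "deepens_input_error")
  }
  test_idx <- with_rng_seed(spec$seed, sort(sample.int(n, sizes[3])))
  rest <- setdiff(seq_len(n), test_idx)
  lapply(seq_len(spec$folds), function(k) {
    val_idx <- with_rng_seed(spec$seed + k, sort(sample(rest, sizes[2])))
    list(train = setdiff(rest, val_idx), val = val_idx, test = test_idx)
  })
}

n_samples <- function(data) {
  if (is.numeric(data) && length(data) == 1) as.integer(data)
  else if (inherits(data, "feature_table")) nrow(data$values)
  else if (inherits(data, "window_set")) nrow(data$values)
  else if (inherits(data, "image_stack")) length(data$images)
  else abort_deepens("cannot count samples of this object", "deepens_input_error")
}

# ---- feature ranking --------------------------------------------------------

#' Rank features by random-forest importance
#'
#' Fits a 100-tree random forest of shallow trees (depth 2 by default) on
#' the imputed, scaled training table and returns all features ordered by
#' decreasing impurity importance, normalised to sum to 1.
#'
#' @param train an imputed, scaled training `feature_table`.
#' @param n_trees number of trees (default 100).
#' @param max_depth maximum tree depth (default 2).
#' @param seed RNG seed for the forest.
#' @return data.frame with columns `feature`, `importance`, ordered by
#'   decreasing importance.
#' @export
rank_features_rf <- function(train, n_trees = 100L, max_depth = 2L, seed = 1L) {
  df <- as.data.frame(train$values)
  df$.label <- factor(train$labels)
  fit <- ranger::ranger(.label ~ ., data = df, num.trees = n_trees,
                        importance = "impurity", max.depth = max_depth,
                        seed = seed, num.threads = 1L)
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             row.names = NULL)
}

# ---- moving windows ---------------------------------------------------------

#' Generate seven-day forward moving-window samples
#'
#' Slides a `window_days`-day window (7 days = 10,080 minutes) over each
#' participant's series, advancing `step_days` per sample; every window
#' inherits the participant's label. A participant with fewer than
#' `window_days` days contributes no samples (logged via message).
#'
#' @param recordings a [recording_set()] (usually imputed).
#' @param window_days window length in days (default 7).
#' @param step_days step between window starts in days (default 1).
#' @param daily_profile if `TRUE`, each window is reduced to a 1440-value
#'   daily profile by averaging the `window_days` values at each
#'   minute-of-day.
#' @return a [window_set()].
#' @export
generate_windows <- function(recordings, window_days = 7L, step_days = 1L,
                             daily_profile = FALSE) {
  stopifnot(window_days >= 1, step_days >= 1)
  wlen <- window_days * MINUTES_PER_DAY
  rows <- list(); meta <- list()
  for (p in recordings$participants) {
    D <- length(p$values) %/% MINUTES_PER_DAY
    if (D < window_days) {
      message(sprintf("participant %s: only %d day(s), window needs %d; skipped",
                      p$id, D, window_days))
      next
    }
    starts <- seq(0L, D - window_days, by = step_days)
    for (s in starts) {
      w <- p$values[(s * MINUTES_PER_DAY + 1L):(s * MINUTES_PER_DAY + wlen)]
      if (daily_profile) w <- rowMeans(matrix(w, nrow = MINUTES_PER_DAY))
      rows[[length(rows) + 1L]] <- w
      meta[[length(meta) + 1L]] <- data.frame(participant_id = p$id,
                                              start_day = s + 1L,
                                              label = p$label)
    }
  }
  if (!length(rows)) {
    return(window_set(matrix(numeric(0), 0,
                             if (daily_profile) MINUTES_PER_DAY else wlen),
                      data.frame(participant_id = character(0),
                                 start_day = integer(0), label = integer(0))))
  }
  window_set(do.call(rbind, rows), do.call(rbind, meta))
}

# ---- image resizing ---------------------------------------------------------

#' Resize all images to a common grayscale shape
#'
#' Bilinear resize to `target[1] x target[2] x 1`; multi-channel inputs are
#' first averaged to one channel; pixel values are clipped to \[0, 1\].
#' Images already at the target size pass through unchanged.
#'
#' @param stack an [image_stack()].
#' @param target output shape, default `c(200, 200, 1)`.
#' @return an `image_stack` of uniformly sized images.
#' @export
resize_images <- function(stack, target = c(200L, 200L, 1L)) {
  th <- as.integer(target[1]); tw <- as.integer(target[2])
  if (th < 1 || tw < 1) {
    abort_deepens("resize target must have positive height and width",
                  "deepens_config_error")
  }
  imgs <- lapply(stack$images, function(im) {
    d <- dim(im)
    if (d[1] < 1 || d[2] < 1) {
      abort_deepens("zero-area image cannot be resized", "deepens_input_error")
    }
    m <- if (d[3] > 1) apply(im, c(1, 2), mean) else im[, , 1]
    if (!(d[1] == th && d[2] == tw)) {
      m <- EBImage::imageData(EBImage::resize(EBImage::Image(m), w = th, h = tw))
    }
    m <- pmin(pmax(m, 0), 1)
    dim(m) <- c(th, tw, 1L)
    m
  })
  image_stack(imgs, stack$labels)
}
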