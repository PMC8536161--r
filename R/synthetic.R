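# Synthetic benchmark emulators: tabular, image and minute-level sequential
# generators reproducing the structural properties of the three benchmark
# datasets (shape, class ratio, missingness mechanism, planted class signal)
# so the whole pipeline is exercisable without external downloads.

# split n into (negative, positive) counts at ratio r = n_neg : n_pos by
# largest remainder (negative first on ties)
apportion_classes <- function(n, class_ratio) {
  if (class_ratio <= 0) abort_deepens("class_ratio must be > 0", "deepens_config_error")
  apportion(n, c(class_ratio / (1 + class_ratio), 1 / (1 + class_ratio), 0))[1:2]
}

#' Specify a synthetic tabular dataset
#'
#' Emulates a clinical feature table: `n_informative` features are shifted
#' by `effect_size` in the positive class, the rest are pure noise, and
#' missing entries are placed completely at random. The `hdu_like` preset
#' pins the shape of a 270-sample, 13-feature table at class ratio 1.25
#' (negative:positive).
#'
#' @param n_samples,n_features table dimensions.
#' @param class_ratio negative:positive ratio (> 0).
#' @param n_informative number of class-informative features.
#' @param effect_size mean shift of informative features in the positive
#'   class (in noise-sd units).
#' @param missing_rate fraction of entries missing completely at random.
#' @param seed RNG seed.
#' @return a `statistical_gen_spec`.
#' @export
statistical_gen_spec <- function(n_samples = 270L, n_features = 13L,
                                 class_ratio = 1.25, n_informative = 5L,
                                 effect_size = 1.0, missing_rate = 0.02,
                                 seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) {
    abort_deepens("missing_rate must be in [0, 1)", "deepens_config_error")
  }
  if (n_informative > n_features) {
    abort_deepens("n_informative cannot exceed n_features", "deepens_config_error")
  }
  if (class_ratio <= 0) abort_deepens("class_ratio must be > 0", "deepens_config_error")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 class_ratio = class_ratio,
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "statistical_gen_spec")
}

#' Generate a synthetic tabular dataset
#'
#' @param spec a [statistical_gen_spec()].
#' @return a [feature_table()]; labels match the requested class ratio to
#'   within one sample, informative columns are named `inf_*`.
#' @export
gen_statistical <- function(spec) {
  counts <- apportion_classes(spec$n_samples, spec$class_ratio)
  if (any(counts == 0)) {
    abort_deepens("class_ratio unachievable: one class would be empty",
                  "deepens_config_error")
  }
  with_rng_seed(spec$seed, {
    y <- sample(rep(c(0L, 1L), counts))
    v <- matrix(stats::rnorm(spec$n_samples * spec$n_features),
                spec$n_samples, spec$n_features)
    if (spec$n_informative > 0) {
      inf <- seq_len(spec$n_informative)
      v[, inf] <- v[, inf] + spec$effect_size * y
    }
    if (spec$missing_rate > 0) {
      miss <- stats::runif(length(v)) < spec$missing_rate
      # never blank out a full column
      for (j in seq_len(ncol(v))) {
        if (all(miss[(j - 1) * nrow(v) + seq_len(nrow(v))])) {
          miss[(j - 1) * nrow(v) + 1L] <- FALSE
        }
      }
      v[miss] <- NA_real_
    }
    nm <- c(if (spec$n_informative > 0) paste0("inf_", seq_len(spec$n_informative)),
            if (spec$n_features > spec$n_informative)
              paste0("noise_", seq_len(spec$n_features - spec$n_informative)))
    feature_table(v, y, nm)
  })
}

#' Specify a synthetic grayscale image dataset
#'
#' Emulates a radiograph-like set: heterogeneous image sizes, a noisy
#' background, and (in the positive class) additive bright blobs whose
#' intensity is `contrast` above background. The `xray_like` preset pins
#' the class ratio 0.37 (normal:disease).
#'
#' @param n_samples number of images.
#' @param class_ratio negative:positive ratio.
#' @param size_range min/max height and width, e.g. `c(24, 40)`.
#' @param contrast blob intensity above background, in \[0, 1\].
#' @param noise_sd background noise standard deviation.
#' @param n_blobs blobs per positive image.
#' @param seed RNG seed.
#' @return an `image_gen_spec`.
#' @export
image_gen_spec <- function(n_samples = 100L, class_ratio = 0.37,
                           size_range = c(24L, 40L), contrast = 0.5,
                           noise_sd = 0.05, n_blobs = 3L, seed = 1L) {
  if (length(size_range) != 2 || size_range[1] < 8 || size_range[2] < size_range[1]) {
    abort_deepens("size_range must be c(min, max) with min >= 8",
                  "deepens_config_error")
  }
  if (contrast < 0 || contrast > 1) {
    abort_deepens("contrast must be in [0, 1]", "deepens_config_error")
  }
  structure(list(n_samples = as.integer(n_samples), class_ratio = class_ratio,
                 size_range = as.integer(size_range), contrast = contrast,
                 noise_sd = noise_sd, n_blobs = as.integer(n_blobs),
                 seed = as.integer(seed)),
            class = "image_gen_spec")
}

#' Generate a synthetic grayscale image dataset
#'
#' @param spec an [image_gen_spec()].
#' @return an [image_stack()] with per-image sizes varying within
#'   `size_range` (exercising [resize_images()]).
#' @export
gen_images <- function(spec) {
  counts <- apportion_classes(spec$n_samples, spec$class_ratio)
  with_rng_seed(spec$seed, {
    y <- sample(rep(c(0L, 1L), counts))
    imgs <- lapply(seq_len(spec$n_samples), function(i) {
      h <- sample(spec$size_range[1]:spec$size_range[2], 1)
      w <- sample(spec$size_range[1]:spec$size_range[2], 1)
      m <- matrix(0.2 + abs(stats::rnorm(h * w, 0, spec$noise_sd)), h, w)
      if (y[i] == 1) {
        for (b in seq_len(spec$n_blobs)) {
          ci <- stats::runif(1, 0.2, 0.8) * h
          cj <- stats::runif(1, 0.2, 0.8) * w
          rad <- stats::runif(1, 0.08, 0.18) * min(h, w)
          d2 <- outer((seq_len(h) - ci)^2, (seq_len(w) - cj)^2, "+")
          m <- m + spec$contrast * exp(-d2 / (2 * rad^2))
        }
      }
      pmin(pmax(m, 0), 1)
    })
    image_stack(imgs, y)
  })
}

#' Specify a synthetic minute-level activity dataset
#'
#' Emulates wrist-actigraphy cohorts: per-participant minute series over
#' whole days, a circadian (24 h sinusoid) component whose amplitude
#' differs by class, nonnegative noise, and contiguous device-off missing
#' segments. The `depresjon_like` preset pins tens of participants at
#' class ratio 2.05 (control:condition), each with at least 7 days.
#'
#' @param n_participants cohort size.
#' @param class_ratio negative:positive participant ratio.
#' @param days_range min/max whole days per participant.
#' @param amplitude_neg,amplitude_pos circadian amplitude per class
#'   (controls move more by day; the condition flattens the rhythm).
#' @param baseline mean activity level.
#' @param noise_sd minute-level noise standard deviation.
#' @param missing_segments expected device-off segments per participant-day.
#' @param missing_segment_minutes mean segment length in minutes
#'   (geometric).
#' @param seed RNG seed.
#' @return a `sequential_gen_spec`.
#' @export
sequential_gen_spec <- function(n_participants = 20L, class_ratio = 2.05,
                                days_range = c(8L, 14L),
                                amplitude_neg = 5, amplitude_pos = 1,
                                baseline = 6, noise_sd = 1,
                                missing_segments = 1.5,
                                missing_segment_minutes = 45,
                                seed = 1L) {
  if (length(days_range) != 2 || days_range[2] < days_range[1] || days_range[1] < 1) {
    abort_deepens("days_range must be c(min, max) with min >= 1",
                  "deepens_config_error")
  }
  if (days_range[2] < 7) {
    abort_deepens("at least one participant must be able to span 7 days",
                  "deepens_config_error")
  }
  structure(list(n_participants = as.integer(n_participants),
                 class_ratio = class_ratio,
                 days_range = as.integer(days_range),
                 amplitude_neg = amplitude_neg, amplitude_pos = amplitude_pos,
                 baseline = baseline, noise_sd = noise_sd,
                 missing_segments = missing_segments,
                 missing_segment_minutes = missing_segment_minutes,
                 seed = as.integer(seed)),
            class = "sequential_gen_spec")
}

#' Generate a synthetic minute-level activity dataset
#'
#' @param spec a [sequential_gen_spec()].
#' @return a [recording_set()]; `NA` runs mark device-off segments.
#' @export
gen_sequential <- function(spec) {
  counts <- apportion_classes(spec$n_participants, spec$class_ratio)
  with_rng_seed(spec$seed, {
    y <- sample(rep(c(0L, 1L), counts))
    parts <- lapply(seq_len(spec$n_participants), function(i) {
      D <- if (spec$days_range[1] == spec$days_range[2]) spec$days_range[1]
           else sample(spec$days_range[1]:spec$days_range[2], 1)
      len <- D * MINUTES_PER_DAY
      minute <- (seq_len(len) - 1) %% MINUTES_PER_DAY
      amp <- if (y[i] == 1) spec$amplitude_pos else spec$amplitude_neg
      v <- spec$baseline + amp * sin(2 * pi * minute / MINUTES_PER_DAY) +
        stats::rnorm(len, 0, spec$noise_sd)
      v <- pmax(v, 0)
      n_seg <- stats::rpois(1, spec$missing_segments * D)
      if (n_seg > 0) {
        for (s in seq_len(n_seg)) {
          start <- sample.int(len, 1)
          dur <- 1L + stats::rgeom(1, 1 / spec$missing_segment_minutes)
          v[start:min(start + dur - 1L, len)] <- NA_real_
        }
        if (all(is.na(v))) v[1] <- spec$baseline   # keep the series imputable
      }
      list(id = sprintf("p%02d", i), label = y[i], values = v)
    })
    recording_set(parts)
  })
}

#' Benchmark-shaped generator presets
#'
#' `hdu_like` — a 270 x 13 tabular set at class ratio 1.25;
#' `xray_like` — a variably sized grayscale image set at class ratio 0.37;
#' `depresjon_like` — tens of minute-level participants at class ratio
#' 2.05 with device-off missing segments. Sample counts other than the
#' pinned shapes may be overridden via `...`.
#'
#' @param preset one of `"hdu_like"`, `"xray_like"`, `"depresjon_like"`.
#' @param seed RNG seed.
#' @param ... overrides passed to the underlying spec constructor.
#' @return the corresponding generator spec.
#' @export
preset_spec <- function(preset = c("hdu_like", "xray_like", "depresjon_like"),
                        seed = 1L, ...) {
  preset <- match.arg(preset)
  over <- list(...)
  args <- switch(preset,
    hdu_like = list(n_samples = 270L, n_features = 13L, class_ratio = 1.25,
                    n_informative = 5L, effect_size = 1.5, missing_rate = 0.02),
    xray_like = list(n_samples = 120L, class_ratio = 0.37,
                     size_range = c(24L, 40L), contrast = 0.5, noise_sd = 0.05),
    depresjon_like = list(n_participants = 22L, class_ratio = 2.05,
                          days_range = c(10L, 16L)))
  args[names(over)] <- over
  args$seed <- seed
  ctor <- switch(preset, hdu_like = statistical_gen_spec,
                 xray_like = image_gen_spec,
                 depresjon_like = sequential_gen_spec)
  do.call(ctor, args)
}

#' Generate a preset dataset and (optionally) write it with a YAML sidecar
#'
#' @param spec any generator spec.
#' @param path optional output path (CSV for tabular/sequential, directory
#'   for images); a `<path>.yaml` sidecar records the spec and seed.
#' @return the generated dataset (invisibly when written).
#' @export
gen_dataset <- function(spec, path = NULL) {
  data <- if (inherits(spec, "statistical_gen_spec")) gen_statistical(spec)
          else if (inherits(spec, "image_gen_spec")) gen_images(spec)
          else if (inherits(spec, "sequential_gen_spec")) gen_sequential(spec)
          else abort_deepens("unknown generator spec", "deepens_config_error")
  if (!is.null(path)) {
    if (inherits(data, "feature_table")) write_feature_table(data, path)
    else if (inherits(data, "image_stack")) write_image_stack(data, path)
    else write_recording_set(data, path)
    yaml::write_yaml(c(list(spec_class = class(spec)[1]), unclass(spec)),
                     paste0(sub("/$", "", path), ".yaml"))
    return(invisible(data))
  }
  data
}
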