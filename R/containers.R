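# Data-type containers: tabular feature tables, grayscale image stacks, and
# minute-resolution per-participant recordings, with plain-text I/O.

#' Tabular binary-classification data with an explicit missingness mask
#'
#' @param values numeric matrix (n x p); `NA` marks missing entries.
#' @param labels binary vector of length n (0/1).
#' @param feature_names optional p feature names (default from columns).
#' @return an object of class `feature_table` with fields `values`,
#'   `missing_mask`, `labels`, `feature_names`.
#' @export
feature_table <- function(values, labels, feature_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1 || ncol(values) < 1) {
    abort_deepens("feature_table needs at least one row and one column",
                  "deepens_input_error")
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(values) || !all(labels %in% c(0L, 1L))) {
    abort_deepens("labels must be one 0/1 value per row", "deepens_input_error")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  }
  colnames(values) <- feature_names
  structure(list(values = values,
                 missing_mask = is.na(values),
                 labels = labels,
                 feature_names = feature_names),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d x %d (%d missing), %d/%d negative/positive\n",
              nrow(x$values), ncol(x$values), sum(x$missing_mask),
              sum(x$labels == 0), sum(x$labels == 1)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset the rows of a feature table
#' @param x a `feature_table`; `i` row indices.
#' @param i row indices.
#' @export
ft_rows <- function(x, i) {
  feature_table(x$values[i, , drop = FALSE], x$labels[i], x$feature_names)
}

#' Read / write a feature table as CSV
#'
#' Layout: header row of feature names plus a final `label` column; an empty
#' cell encodes a missing value.
#' @param x a `feature_table`; `path` a file path.
#' @export
write_feature_table <- function(x, path) {
  df <- as.data.frame(x$values)
  df$label <- x$labels
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @param path file path.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) {
    abort_deepens("feature table CSV must have a 'label' column", "deepens_input_error")
  }
  lab <- df$label
  df$label <- NULL
  feature_table(as.matrix(df), lab, names(df))
}

# ---- image stacks ----------------------------------------------------------

#' A set of grayscale images with binary labels
#'
#' Images are stored as a list of `h x w x 1` arrays with pixel values in
#' \[0, 1\]; heterogeneous sizes are allowed until [resize_images()].
#'
#' @param images list of 2-d matrices or `h x w x 1` arrays.
#' @param labels binary vector, one per image.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(images, labels) {
  if (length(images) != length(labels)) {
    abort_deepens("one label per image required", "deepens_input_error")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    abort_deepens("image labels must be 0/1", "deepens_input_error")
  }
  images <- lapply(images, function(im) {
    if (is.matrix(im)) dim(im) <- c(dim(im), 1L)
    if (length(dim(im)) != 3) {
      abort_deepens("images must be h x w (x 1) arrays", "deepens_input_error")
    }
    im
  })
  structure(list(images = images, labels = labels), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  sz <- vapply(x$images, function(im) paste(dim(im)[1:2], collapse = "x"), "")
  cat(sprintf("<image_stack> %d images (%s%s), %d/%d negative/positive\n",
              length(x$images), paste(utils::head(unique(sz), 3), collapse = ", "),
              if (length(unique(sz)) > 3) ", ..." else "",
              sum(x$labels == 0), sum(x$labels == 1)))
  invisible(x)
}

# stack homogeneous-size images into an (n, h, w, 1) array for the CNN engine
stack_to_array <- function(stack) {
  d <- dim(stack$images[[1]])
  if (!all(vapply(stack$images, function(im) identical(dim(im), d), TRUE))) {
    abort_deepens("images must share one size (resize_images first)",
                  "deepens_input_error")
  }
  n <- length(stack$images)
  out <- array(0, c(n, d))
  for (i in seq_len(n)) out[i, , , ] <- stack$images[[i]]
  out
}

#' Read / write an image stack as a directory of PNG files plus labels.csv
#'
#' `labels.csv` has columns `file,label`; pixel values are stored as 8-bit
#' grayscale PNG.
#' @param stack an `image_stack`; `dir` a directory path.
#' @export
write_image_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("img_%04d.png", seq_along(stack$images))
  for (i in seq_along(stack$images)) {
    png::writePNG(pmin(pmax(stack$images[[i]][, , 1], 0), 1),
                  file.path(dir, files[i]))
  }
  utils::write.csv(data.frame(file = files, label = stack$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_image_stack
#' @param dir directory path.
#' @export
read_image_stack <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  imgs <- lapply(file.path(dir, lab$file), function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- apply(m, c(1, 2), mean)
    m
  })
  image_stack(imgs, lab$label)
}

# ---- minute-level recordings ------------------------------------------------

MINUTES_PER_DAY <- 1440L

#' Per-participant minute-resolution activity recordings
#'
#' Each participant carries a minute-indexed series spanning whole days
#' (length `D * 1440`); `NA` marks device-off (missing) minutes. The
#' minute-of-day of entry `i` is `(i - 1) %% 1440`.
#'
#' @param participants list of lists with fields `id`, `label` (0/1),
#'   `values` (numeric, `NA` = missing, length a multiple of 1440).
#' @return an object of class `recording_set`.
#' @export
recording_set <- function(participants) {
  for (p in participants) {
    if (length(p$values) %% MINUTES_PER_DAY != 0 || length(p$values) == 0) {
      abort_deepens(sprintf(
        "participant %s: series length must be a positive multiple of 1440", p$id),
        "deepens_input_error")
    }
  }
  structure(list(participants = lapply(participants, function(p) {
    list(id = as.character(p$id), label = as.integer(p$label),
         values = as.numeric(p$values), missing_mask = is.na(p$values))
  })), class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  days <- vapply(x$participants, function(p) length(p$values) / MINUTES_PER_DAY, 0)
  labs <- vapply(x$participants, function(p) p$label, 0L)
  cat(sprintf("<recording_set> %d participants, %g-%g days, %d/%d negative/positive\n",
              length(x$participants), min(days), max(days),
              sum(labs == 0), sum(labs == 1)))
  invisible(x)
}

#' Read / write recordings as long-format CSV
#'
#' Columns: `participant_id`, `timestamp` (ISO-8601, minute resolution),
#' `activity` (empty = missing), `label`. Timestamps are positional: series
#' start at `origin` at 00:00 and advance one minute per row.
#' @param rec a `recording_set`; `path` a file path.
#' @param origin date of the first minute (used only to render timestamps).
#' @export
write_recording_set <- function(rec, path, origin = "2020-01-06") {
  t0 <- as.POSIXct(paste(origin, "00:00:00"), tz = "UTC")
  rows <- lapply(rec$participants, function(p) {
    data.frame(participant_id = p$id,
               timestamp = format(t0 + 60 * (seq_along(p$values) - 1),
                                  "%Y-%m-%dT%H:%M:%S"),
               activity = p$values,
               label = p$label)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_recording_set
#' @param path file path.
#' @export
read_recording_set <- function(path) {
  df <- utils::read.csv(path)
  parts <- lapply(split(df, df$participant_id), function(d) {
    d <- d[order(d$timestamp), ]
    list(id = d$participant_id[1], label = d$label[1], values = d$activity)
  })
  recording_set(unname(parts))
}

#' Moving-window samples generated from recordings
#'
#' @param values numeric matrix, one window per row.
#' @param meta data.frame with `participant_id`, `start_day`, `label`.
#' @return an object of class `window_set`.
#' @export
window_set <- function(values, meta) {
  stopifnot(nrow(values) == nrow(meta))
  structure(list(values = values, meta = meta), class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows x %d minutes from %d participants\n",
              nrow(x$values), ncol(x$values), length(unique(x$meta$participant_id))))
  invisible(x)
}
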