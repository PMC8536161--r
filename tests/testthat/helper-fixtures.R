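# Fixture builders shared across the suite. Everything is generated in code
# under fixed seeds; no stored data files.

# linearly separable two-feature data with a wide margin
separable_data <- function(n = 200, seed = 1, margin = 1) {
  set.seed(seed)
  y <- rep_len(c(0L, 1L), n)
  x <- matrix(rnorm(n * 2, sd = 0.3), n)
  x[, 1] <- x[, 1] + ifelse(y == 1, margin, -margin)
  list(x = x, y = y)
}

# a small fitted probability MLP for composition tests
fitted_mlp <- function(seed = 1, n = 80, epochs = 15) {
  d <- separable_data(n, seed = seed + 500)
  spec <- clu_spec("mlp", c(4L, 1L), epochs = epochs, batch_size = 16L,
                   initial_lr = 0.05, seed = seed)
  train_clu(build_clu(spec), d, list(x = d$x[1:20, ], y = d$y[1:20]))$clu
}

# recordings with hand-controllable values: one participant, D days,
# constant value per day unless overridden
make_recording <- function(id = "p1", label = 0L, day_values, missing_at = NULL) {
  v <- rep(day_values, each = 1440)
  if (!is.null(missing_at)) v[missing_at] <- NA_real_
  list(id = id, label = label, values = v)
}

# central-difference gradient of a scalar loss wrt a nested parameter list
numeric_gradient <- function(fn, params, eps = 1e-5) {
  set_at <- function(p, path, idx, val) {
    if (length(path) == 1) { p[[path[[1]]]][idx] <- val; return(p) }
    p[[path[[1]]]] <- set_at(p[[path[[1]]]], path[-1], idx, val)
    p
  }
  walk <- function(p, path = list()) {
    if (is.list(p)) {
      out <- lapply(seq_along(p), function(i) {
        key <- if (!is.null(names(p)) && nzchar(names(p)[i])) names(p)[i] else i
        walk(p[[key]], c(path, list(key)))
      })
      names(out) <- names(p)
      return(out)
    }
    g <- array(0, dim(as.array(p)))
    for (i in seq_along(p)) {
      g[i] <- (fn(set_at(params, path, i, p[i] + eps)) -
               fn(set_at(params, path, i, p[i] - eps))) / (2 * eps)
    }
    g
  }
  walk(params)
}
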