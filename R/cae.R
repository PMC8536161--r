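# Convolutional autoencoder: converts images into fixed-length feature rows
# via a compressed bottleneck, so classical (tabular) learners can be run on
# image data. Two conv+pool encoder blocks, a dense bottleneck, and a
# mirrored upsample+conv decoder with sigmoid pixels.

cae_init_params <- function(h, w, filters, bottleneck_dim, seed) {
  h4 <- h %/% 4L; w4 <- w %/% 4L
  with_rng_seed(seed, list(
    c1 = conv_init(3L, 1L, filters[1]),
    c2 = conv_init(3L, filters[1], filters[2]),
    enc = dense_init(h4 * w4 * filters[2], bottleneck_dim),
    dec = dense_init(bottleneck_dim, h4 * w4 * filters[2]),
    d1 = conv_init(3L, filters[2], filters[2]),
    d2 = conv_init(3L, filters[2], filters[1]),
    out = conv_init(3L, filters[1], 1L)
  ))
}

cae_forward <- function(par, X, want_cache = FALSE) {
  d <- dim(X); n <- d[1]
  a1 <- act_forward(conv_forward(X, par$c1), "relu")
  p1 <- maxpool_forward(a1)
  a2 <- act_forward(conv_forward(p1$out, par$c2), "relu")
  p2 <- maxpool_forward(a2)
  pd <- dim(p2$out)
  flat <- p2$out; dim(flat) <- c(n, prod(pd[-1]))
  z <- dense_forward(flat, par$enc)                       # linear bottleneck
  e <- act_forward(dense_forward(z, par$dec), "relu")
  E <- e; dim(E) <- pd
  u1 <- upsample_forward(E)
  b1 <- act_forward(conv_forward(u1, par$d1), "relu")
  u2 <- upsample_forward(b1)
  b2 <- act_forward(conv_forward(u2, par$d2), "relu")
  out <- act_forward(conv_forward(b2, par$out), "sigmoid")
  if (!want_cache) return(list(out = out, z = z))
  list(out = out, z = z, cache = list(X = X, a1 = a1, p1 = p1, a2 = a2, p2 = p2,
                                      pd = pd, flat = flat, e = e, u1 = u1,
                                      b1 = b1, u2 = u2, b2 = b2))
}

cae_backward <- function(par, fwd, X) {
  cc <- fwd$cache
  ntot <- length(X)
  dpre <- 2 * (fwd$out - X) / ntot * fwd$out * (1 - fwd$out)
  g <- list()
  bo <- conv_backward(dpre, cc$b2, par$out)
  g$out <- list(W = bo$dW, b = bo$db)
  db2 <- act_backward(bo$dX, cc$b2, "relu")
  b2b <- conv_backward(db2, cc$u2, par$d2)
  g$d2 <- list(W = b2b$dW, b = b2b$db)
  du2 <- upsample_backward(b2b$dX, dim(cc$b1))
  db1 <- act_backward(du2, cc$b1, "relu")
  b1b <- conv_backward(db1, cc$u1, par$d1)
  g$d1 <- list(W = b1b$dW, b = b1b$db)
  dE <- upsample_backward(b1b$dX, cc$pd)
  de <- dE; dim(de) <- dim(cc$e)
  de <- act_backward(de, cc$e, "relu")
  bd <- dense_backward(de, fwd$z, par$dec)
  g$dec <- list(W = bd$dW, b = bd$db)
  be <- dense_backward(bd$dX, cc$flat, par$enc)
  g$enc <- list(W = be$dW, b = be$db)
  dp2 <- be$dX; dim(dp2) <- cc$pd
  da2 <- maxpool_backward(dp2, cc$p2, dim(cc$a2))
  da2 <- act_backward(da2, cc$a2, "relu")
  b2c <- conv_backward(da2, cc$p1$out, par$c2)
  g$c2 <- list(W = b2c$dW, b = b2c$db)
  da1 <- maxpool_backward(b2c$dX, cc$p1, dim(cc$a1))
  da1 <- act_backward(da1, cc$a1, "relu")
  b1c <- conv_backward(da1, cc$X, par$c1)
  g$c1 <- list(W = b1c$dW, b = b1c$db)
  g[names(par)]
}

#' Fit a convolutional autoencoder on training images
#'
#' The encoder (two 3x3 conv + 2x2 max-pool blocks, then a dense linear
#' bottleneck of `bottleneck_dim` units) learns a compressed representation
#' by minimising pixel-wise reconstruction MSE through a mirrored decoder.
#' Fit it on the training partition only; extraction then uses the frozen
#' weights of the best (lowest training MSE) epoch.
#'
#' @param train_images an [image_stack()] of uniformly sized images with
#'   height and width divisible by 4 and pixels in \[0, 1\].
#' @param bottleneck_dim length of the extracted feature vector (default 32).
#' @param epochs training epochs (default 20).
#' @param batch_size mini-batch size (default 16).
#' @param lr Adam learning rate (default 1e-3).
#' @param filters filter counts of the two encoder blocks (default 16, 8).
#' @param seed RNG seed.
#' @return a `cae_model` with the frozen parameters and an epoch-wise
#'   reconstruction-loss log.
#' @export
cae_fit <- function(train_images, bottleneck_dim = 32L, epochs = 20L,
                    batch_size = 16L, lr = 1e-3, filters = c(16L, 8L),
                    seed = 1L) {
  X <- stack_to_array(train_images)
  d <- dim(X)
  if (d[2] %% 4 != 0 || d[3] %% 4 != 0) {
    abort_deepens("image height/width must be divisible by 4", "deepens_config_error")
  }
  par <- cae_init_params(d[2], d[3], filters, bottleneck_dim, seed)
  n <- d[1]
  losses <- numeric(epochs)
  best <- Inf; best_par <- par
  with_rng_seed(seed + 104729L, {
    state <- opt_init(par)
    for (e in seq_len(epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      bl <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- perm[starts[bi]:min(starts[bi] + batch_size - 1L, n)]
        xb <- X[idx, , , , drop = FALSE]
        fwd <- cae_forward(par, xb, want_cache = TRUE)
        bl[bi] <- mean((fwd$out - xb)^2)
        grads <- cae_backward(par, fwd, xb)
        st <- opt_step(par, grads, state, "adam", lr)
        par <- st$params; state <- st$state
      }
      losses[e] <- mean(bl)
      if (!is.finite(losses[e])) {
        abort_deepens("CAE training diverged (non-finite loss)",
                      "deepens_diverged_error")
      }
      if (losses[e] < best) { best <- losses[e]; best_par <- par }
    }
  })
  structure(list(parameters = best_par, bottleneck_dim = as.integer(bottleneck_dim),
                 input_shape = d[-1], filters = as.integer(filters),
                 loss_log = data.frame(epoch = seq_len(epochs),
                                       train_mse = losses),
                 is_fitted = TRUE, seed = as.integer(seed)),
            class = "cae_model")
}

#' Extract bottleneck features from images with a fitted CAE
#'
#' Deterministic given the frozen weights: each image maps to one row of
#' `bottleneck_dim` features.
#'
#' @param model a fitted [cae_fit()] model.
#' @param images an `image_stack` with the model's input size.
#' @return a [feature_table()] of `n x bottleneck_dim` features carrying the
#'   stack's labels.
#' @export
cae_extract <- function(model, images) {
  if (!inherits(model, "cae_model") || !isTRUE(model$is_fitted)) {
    abort_deepens("CAE model is not fitted", "deepens_state_error")
  }
  X <- stack_to_array(images)
  if (!identical(dim(X)[-1], as.integer(model$input_shape))) {
    abort_deepens("image size does not match the fitted CAE", "deepens_input_error")
  }
  Z <- cae_forward(model$parameters, X)$z
  colnames(Z) <- paste0("cae_", seq_len(ncol(Z)))
  feature_table(Z, images$labels)
}
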