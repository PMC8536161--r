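# Internal neural engine: dense / convolutional / gated-recurrent layers with
# reverse-mode gradients, written against base R matrix ops. All randomness is
# drawn from an explicitly seeded Mersenne-Twister stream so that training is
# bit-reproducible (same seed, same data => same parameters).

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

glorot_uniform <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

# ---- activations -----------------------------------------------------------

act_forward <- function(z, act) {
  switch(act,
    relu    = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-pmin(pmax(z, -40), 40))),
    tanh    = tanh(z),
    linear  = z,
    stop("unknown activation: ", act, call. = FALSE)
  )
}

# derivative expressed through the activation output `a`
act_backward <- function(da, a, act) {
  switch(act,
    relu    = da * (a > 0),
    sigmoid = da * a * (1 - a),
    tanh    = da * (1 - a^2),
    linear  = da,
    stop("unknown activation: ", act, call. = FALSE)
  )
}

sigmoid_ <- function(z) 1 / (1 + exp(-pmin(pmax(z, -40), 40)))

# ---- losses ----------------------------------------------------------------

loss_value <- function(pred, y, loss) {
  if (loss == "binary_cross_entropy") {
    p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    mean((pred - y)^2)
  }
}

# gradient wrt the PRE-activation of the output layer, folding in the output
# nonlinearity (sigmoid for BCE, identity for MSE)
loss_output_grad <- function(pred, y, loss) {
  n <- length(y)
  if (loss == "binary_cross_entropy") (pred - y) / n else 2 * (pred - y) / n
}

# ---- dense layers ----------------------------------------------------------

dense_init <- function(n_in, n_out) {
  list(W = glorot_uniform(n_in, n_out, c(n_in, n_out)),
       b = numeric(n_out))
}

dense_forward <- function(X, p) {
  sweep(X %*% p$W, 2, p$b, "+")
}

dense_backward <- function(dZ, X, p) {
  list(dW = crossprod(X, dZ),
       db = colSums(dZ),
       dX = dZ %*% t(p$W))
}

# ---- 2-d convolution (3x3, stride 1, "same" padding) -----------------------

conv_init <- function(k, c_in, c_out) {
  fan_in <- k * k * c_in
  fan_out <- k * k * c_out
  list(W = glorot_uniform(fan_in, fan_out, c(k, k, c_in, c_out)),
       b = numeric(c_out))
}

pad_nhwc <- function(X, p) {
  d <- dim(X)
  out <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- X
  out
}

conv_forward <- function(X, par) {
  d <- dim(X)                       # (n, h, w, c_in)
  k <- dim(par$W)[1]
  c_in <- dim(par$W)[3]; c_out <- dim(par$W)[4]
  p <- (k - 1L) %/% 2L
  Xp <- pad_nhwc(X, p)
  n <- d[1]; h <- d[2]; w <- d[3]
  acc <- matrix(0, n * h * w, c_out)
  for (di in 0:(k - 1)) {
    for (dj in 0:(k - 1)) {
      Xs <- Xp[, (1 + di):(h + di), (1 + dj):(w + dj), , drop = FALSE]
      dim(Xs) <- c(n * h * w, c_in)
      acc <- acc + Xs %*% matrix(par$W[di + 1, dj + 1, , ], c_in, c_out)
    }
  }
  acc <- sweep(acc, 2, par$b, "+")
  dim(acc) <- c(n, h, w, c_out)
  acc
}

conv_backward <- function(dOut, X, par) {
  d <- dim(X)
  k <- dim(par$W)[1]
  c_in <- dim(par$W)[3]; c_out <- dim(par$W)[4]
  p <- (k - 1L) %/% 2L
  n <- d[1]; h <- d[2]; w <- d[3]
  Xp <- pad_nhwc(X, p)
  dXp <- array(0, dim(Xp))
  dO <- dOut; dim(dO) <- c(n * h * w, c_out)
  dW <- array(0, dim(par$W))
  for (di in 0:(k - 1)) {
    for (dj in 0:(k - 1)) {
      Xs <- Xp[, (1 + di):(h + di), (1 + dj):(w + dj), , drop = FALSE]
      dim(Xs) <- c(n * h * w, c_in)
      dW[di + 1, dj + 1, , ] <- crossprod(Xs, dO)
      dXs <- dO %*% t(matrix(par$W[di + 1, dj + 1, , ], c_in, c_out))
      dim(dXs) <- c(n, h, w, c_in)
      dXp[, (1 + di):(h + di), (1 + dj):(w + dj), ] <-
        dXp[, (1 + di):(h + di), (1 + dj):(w + dj), , drop = FALSE] + dXs
    }
  }
  list(dW = dW, db = colSums(dO),
       dX = dXp[, (p + 1):(p + h), (p + 1):(p + w), , drop = FALSE])
}

# ---- 2x2 max pooling / nearest upsampling ----------------------------------

maxpool_forward <- function(X) {
  d <- dim(X)
  i1 <- seq(1, d[2] - 1, 2); j1 <- seq(1, d[3] - 1, 2)
  s00 <- X[, i1, j1, , drop = FALSE]; s01 <- X[, i1, j1 + 1, , drop = FALSE]
  s10 <- X[, i1 + 1, j1, , drop = FALSE]; s11 <- X[, i1 + 1, j1 + 1, , drop = FALSE]
  out <- pmax(s00, s01, s10, s11)
  list(out = out, slices = list(s00, s01, s10, s11))
}

maxpool_backward <- function(dOut, fw, in_dim) {
  out <- pmax(fw$slices[[1]], fw$slices[[2]], fw$slices[[3]], fw$slices[[4]])
  dX <- array(0, in_dim)
  i1 <- seq(1, in_dim[2] - 1, 2); j1 <- seq(1, in_dim[3] - 1, 2)
  used <- array(FALSE, dim(out))
  offs <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  for (s in 1:4) {
    m <- (fw$slices[[s]] == out) & !used
    used <- used | m
    dX[, i1 + offs[[s]][1], j1 + offs[[s]][2], ] <- dOut * m
  }
  dX
}

upsample_forward <- function(X) {
  d <- dim(X)
  out <- array(0, c(d[1], d[2] * 2, d[3] * 2, d[4]))
  i1 <- seq(1, d[2] * 2 - 1, 2); j1 <- seq(1, d[3] * 2 - 1, 2)
  out[, i1, j1, ] <- X; out[, i1 + 1, j1, ] <- X
  out[, i1, j1 + 1, ] <- X; out[, i1 + 1, j1 + 1, ] <- X
  out
}

upsample_backward <- function(dOut, in_dim) {
  i1 <- seq(1, in_dim[2] * 2 - 1, 2); j1 <- seq(1, in_dim[3] * 2 - 1, 2)
  dOut[, i1, j1, , drop = FALSE] + dOut[, i1 + 1, j1, , drop = FALSE] +
    dOut[, i1, j1 + 1, , drop = FALSE] + dOut[, i1 + 1, j1 + 1, , drop = FALSE]
}

# ---- gated recurrent layer with additive attention pooling -----------------

gru_init <- function(n_in, units, attn_dim = max(8L, units %/% 2L)) {
  g <- function(a, b, dims) glorot_uniform(a, b, dims)
  list(
    Wz = g(n_in, units, c(n_in, units)), Uz = g(units, units, c(units, units)), bz = numeric(units),
    Wr = g(n_in, units, c(n_in, units)), Ur = g(units, units, c(units, units)), br = numeric(units),
    Wh = g(n_in, units, c(n_in, units)), Uh = g(units, units, c(units, units)), bh = numeric(units),
    Wa = g(units, attn_dim, c(units, attn_dim)), ba = numeric(attn_dim),
    va = g(attn_dim, 1, c(attn_dim, 1))
  )
}

# X: (n, T, c). Returns context vector (n, units) plus caches for backprop.
gru_forward <- function(X, p) {
  d <- dim(X); n <- d[1]; Tn <- d[2]
  units <- ncol(p$Wz)
  h <- matrix(0, n, units)
  cache <- vector("list", Tn)
  H <- array(0, c(n, Tn, units))
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], n)
    z <- sigmoid_(xt %*% p$Wz + h %*% p$Uz + rep(p$bz, each = n))
    r <- sigmoid_(xt %*% p$Wr + h %*% p$Ur + rep(p$br, each = n))
    hh <- tanh(xt %*% p$Wh + (r * h) %*% p$Uh + rep(p$bh, each = n))
    h_new <- (1 - z) * h + z * hh
    cache[[t]] <- list(xt = xt, h_prev = h, z = z, r = r, hh = hh)
    h <- h_new
    H[, t, ] <- h
  }
  # additive attention: e_t = tanh(H_t Wa + ba) va
  A <- array(0, c(n, Tn, ncol(p$Wa)))
  E <- matrix(0, n, Tn)
  for (t in seq_len(Tn)) {
    At <- tanh(matrix(H[, t, ], n) %*% p$Wa + rep(p$ba, each = n))
    A[, t, ] <- At
    E[, t] <- At %*% p$va
  }
  Emax <- apply(E, 1, max)
  W <- exp(E - Emax)
  alpha <- W / rowSums(W)
  ctx <- matrix(0, n, units)
  for (t in seq_len(Tn)) ctx <- ctx + alpha[, t] * matrix(H[, t, ], n)
  list(ctx = ctx, H = H, A = A, alpha = alpha, cache = cache)
}

gru_backward <- function(dctx, X, p, fw) {
  d <- dim(X); n <- d[1]; Tn <- d[2]
  units <- ncol(p$Wz)
  H <- fw$H; alpha <- fw$alpha; A <- fw$A
  dH <- array(0, c(n, Tn, units))
  dalpha <- matrix(0, n, Tn)
  for (t in seq_len(Tn)) {
    Ht <- matrix(H[, t, ], n)
    dalpha[, t] <- rowSums(dctx * Ht)
    dH[, t, ] <- alpha[, t] * dctx
  }
  # softmax backward
  dE <- alpha * (dalpha - rowSums(alpha * dalpha))
  g <- lapply(p, function(x) array(0, dim(as.array(x))))
  for (t in seq_len(Tn)) {
    At <- matrix(A[, t, ], n)
    dAt <- (dE[, t] %*% t(p$va[, 1, drop = FALSE])) * (1 - At^2)
    dAt <- matrix(dAt, n)
    g$Wa <- g$Wa + crossprod(matrix(H[, t, ], n), dAt)
    g$ba <- g$ba + colSums(dAt)
    g$va <- g$va + crossprod(At, dE[, t, drop = FALSE])
    dH[, t, ] <- matrix(dH[, t, ], n) + dAt %*% t(p$Wa)
  }
  carry <- matrix(0, n, units)
  for (t in rev(seq_len(Tn))) {
    cc <- fw$cache[[t]]
    dh <- matrix(dH[, t, ], n) + carry
    dhh <- dh * cc$z
    dz <- dh * (cc$hh - cc$h_prev)
    dh_prev <- dh * (1 - cc$z)
    dhh_pre <- dhh * (1 - cc$hh^2)
    g$Wh <- g$Wh + crossprod(cc$xt, dhh_pre)
    g$Uh <- g$Uh + crossprod(cc$r * cc$h_prev, dhh_pre)
    g$bh <- g$bh + colSums(dhh_pre)
    drh <- dhh_pre %*% t(p$Uh)
    dr <- drh * cc$h_prev
    dh_prev <- dh_prev + drh * cc$r
    dz_pre <- dz * cc$z * (1 - cc$z)
    dr_pre <- dr * cc$r * (1 - cc$r)
    g$Wz <- g$Wz + crossprod(cc$xt, dz_pre)
    g$Uz <- g$Uz + crossprod(cc$h_prev, dz_pre)
    g$bz <- g$bz + colSums(dz_pre)
    g$Wr <- g$Wr + crossprod(cc$xt, dr_pre)
    g$Ur <- g$Ur + crossprod(cc$h_prev, dr_pre)
    g$br <- g$br + colSums(dr_pre)
    carry <- dh_prev + dz_pre %*% t(p$Uz) + dr_pre %*% t(p$Ur)
  }
  g
}

# ---- optimizers ------------------------------------------------------------

opt_init <- function(params) {
  list(t = 0L,
       m = rapply(params, function(x) array(0, dim(as.array(x))), how = "replace"),
       v = rapply(params, function(x) array(0, dim(as.array(x))), how = "replace"))
}

# params/grads are arbitrarily nested lists of numeric arrays with identical shape
opt_step <- function(params, grads, state, optimizer, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (optimizer == "sgd") {
    params <- map2_num(params, grads, function(p, g) p - lr * g)
    return(list(params = params, state = state))
  }
  state$t <- state$t + 1L
  state$m <- map2_num(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_num(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map2_num(state$m, state$v, function(m, v) (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map2_num(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}

# L2 weight decay on multi-dimensional parameter arrays (weight matrices and
# kernels); bias vectors are left undecayed
add_weight_decay <- function(grads, params, l2) {
  map2_num(grads, params, function(g, p) {
    if (!is.null(dim(p)) && length(dim(p)) > 1) g + l2 * p else g
  })
}

# elementwise binary map over identically shaped nested lists of arrays
map2_num <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(map2_num, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    r <- f(a, b)
    if (!is.null(dim(a))) dim(r) <- dim(a)
    r
  }
}
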