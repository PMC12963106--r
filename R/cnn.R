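# 1-D convolutional network engine.
#
# Activations flow through the network as (L*B) x C matrices: rows index
# time-within-batch-item (item-major: row = (b-1)*L + l), columns index
# channels. Convolutions are evaluated as im2col patch-matrix times weight-
# matrix products so that all heavy arithmetic is BLAS matrix multiplication.
# Only what the model needs is implemented: valid-padding convolution,
# batch normalization, ReLU, width-2/stride-2 max pooling, dropout, global
# average pooling, dense layers, a sigmoid head with weighted binary
# cross-entropy, and Adam.

.he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

# Build parameter list for a given spec; input_length fixes all layer sizes.
.cnn_init_params <- function(spec) {
  params <- list(conv = list(), bn = list())
  L <- spec$input_length
  c_in <- 1L
  for (i in seq_len(spec$n_conv_layers)) {
    c_out <- spec$channels[i]
    L <- L - spec$kernel_size + 1L
    if (L < 1) stop("input too short for ", spec$n_conv_layers, " conv layers")
    params$conv[[i]] <- list(
      W = .he_init(spec$kernel_size * c_in, c_out, spec$kernel_size * c_in),
      b = rep(0, c_out))
    params$bn[[i]] <- list(gamma = rep(1, c_out), beta = rep(0, c_out),
                           run_mean = rep(0, c_out), run_var = rep(1, c_out))
    L <- L %/% 2L
    if (L < 1) stop("input too short for ", spec$n_conv_layers, " conv layers")
    c_in <- c_out
  }
  params$W1 <- .he_init(c_in, spec$hidden_units, c_in)
  params$b1 <- rep(0, spec$hidden_units)
  params$W2 <- .he_init(spec$hidden_units, 1L, spec$hidden_units)
  params$b2 <- 0
  params
}

# im2col row-index vectors for one (L, B) geometry, one per kernel offset.
.im2col_index <- function(L, L_out, B, K) {
  base <- (0:(B - 1)) * L
  lapply(seq_len(K), function(k) as.vector(outer(seq_len(L_out) + k - 1L, base, "+")))
}

.conv_forward <- function(mat, L, B, W, b, K, c_in) {
  L_out <- L - K + 1L
  M <- matrix(0, L_out * B, K * c_in)
  idx <- .im2col_index(L, L_out, B, K)
  for (k in seq_len(K)) {
    M[, ((k - 1L) * c_in + 1L):(k * c_in)] <- mat[idx[[k]], , drop = FALSE]
  }
  Z <- M %*% W
  Z <- sweep(Z, 2, b, "+")
  list(out = Z, M = M, L_out = L_out)
}

.conv_backward <- function(dZ, M, W, L, B, K, c_in) {
  dW <- crossprod(M, dZ)
  db <- colSums(dZ)
  dM <- tcrossprod(dZ, W)
  L_out <- nrow(dZ) / B
  dmat <- matrix(0, L * B, c_in)
  idx <- .im2col_index(L, L_out, B, K)
  for (k in seq_len(K)) {
    block <- dM[, ((k - 1L) * c_in + 1L):(k * c_in), drop = FALSE]
    dmat[idx[[k]], ] <- dmat[idx[[k]], , drop = FALSE] + block
  }
  list(dmat = dmat, dW = dW, db = db)
}

.bn_forward <- function(mat, bn, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(mat)
    va <- colMeans(sweep(mat, 2, mu)^2)
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    bn$run_var <- (1 - momentum) * bn$run_var + momentum * va
  } else {
    mu <- bn$run_mean
    va <- bn$run_var
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(mat, 2, mu), 2, inv_sd, "*")
  out <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(out = out, xhat = xhat, inv_sd = inv_sd, bn = bn)
}

.bn_backward <- function(dout, cache, gamma) {
  n <- nrow(dout)
  dxhat <- sweep(dout, 2, gamma, "*")
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  # Compact fused form of the batch-norm gradient.
  t1 <- colSums(dxhat)
  t2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2, t1 / n) - sweep(cache$xhat, 2, t2 / n, "*")
  dx <- sweep(dx, 2, cache$inv_sd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.pool_index <- function(L, B) {
  L_p <- L %/% 2L
  base <- (0:(B - 1)) * L
  i1 <- as.vector(outer(seq(1L, 2L * L_p, by = 2L), base, "+"))
  list(i1 = i1, i2 = i1 + 1L, L_p = L_p)
}

.maxpool_forward <- function(mat, L, B) {
  px <- .pool_index(L, B)
  m1 <- mat[px$i1, , drop = FALSE]
  m2 <- mat[px$i2, , drop = FALSE]
  take1 <- m1 >= m2
  list(out = pmax(m1, m2), take1 = take1, px = px)
}

.maxpool_backward <- function(dout, cache, L, B, C) {
  dmat <- matrix(0, L * B, C)
  d1 <- dout * cache$take1
  d2 <- dout * !cache$take1
  dmat[cache$px$i1, ] <- d1
  dmat[cache$px$i2, ] <- d2
  dmat
}

# Forward pass. X: B x input_length matrix of (already scaled) segments.
# Returns probabilities and, when training, the cache for backprop.
.cnn_forward <- function(params, spec, X, training = FALSE, drop_masks = NULL) {
  B <- nrow(X)
  L <- ncol(X)
  mat <- matrix(t(X), ncol = 1L)          # (L*B) x 1, item-major rows
  c_in <- 1L
  caches <- vector("list", spec$n_conv_layers)
  for (i in seq_len(spec$n_conv_layers)) {
    cv <- .conv_forward(mat, L, B, params$conv[[i]]$W, params$conv[[i]]$b,
                        spec$kernel_size, c_in)
    bnf <- .bn_forward(cv$out, params$bn[[i]], training)
    params$bn[[i]] <- bnf$bn
    relu_mask <- bnf$out > 0
    act <- bnf$out * relu_mask
    mp <- .maxpool_forward(act, cv$L_out, B)
    out <- mp$out
    mask <- NULL
    if (training && spec$dropout_rate > 0) {
      mask <- drop_masks[[i]]
      out <- out * mask / (1 - spec$dropout_rate)
    }
    caches[[i]] <- list(M = cv$M, bn_cache = bnf, relu_mask = relu_mask,
                        mp = mp, L_in = L, L_conv = cv$L_out, c_in = c_in,
                        drop_mask = mask)
    mat <- out
    L <- mp$px$L_p
    c_in <- spec$channels[i]
  }
  # Global average pool over time -> B x C features.
  grp <- rep(seq_len(B), each = L)
  feat <- rowsum(mat, grp) / L
  h_pre <- sweep(feat %*% params$W1, 2, params$b1, "+")
  h <- h_pre * (h_pre > 0)
  z <- as.vector(h %*% params$W2) + params$b2
  p <- 1 / (1 + exp(-z))
  list(p = p, z = z,
       cache = if (training) list(caches = caches, feat = feat, h = h,
                                  h_pre = h_pre, L_final = L, B = B) else NULL,
       params = params)
}

# Backward pass from dL/dz (vector length B); returns gradients shaped like
# params.
.cnn_backward <- function(params, spec, fwd, dz) {
  cache <- fwd$cache
  B <- cache$B
  grads <- list(conv = vector("list", spec$n_conv_layers),
                bn = vector("list", spec$n_conv_layers))
  dW2 <- crossprod(cache$h, matrix(dz, ncol = 1))
  db2 <- sum(dz)
  dh <- (matrix(dz, ncol = 1) %*% t(params$W2)) * (cache$h_pre > 0)
  dW1 <- crossprod(cache$feat, dh)
  db1 <- colSums(dh)
  dfeat <- tcrossprod(dh, params$W1)
  L <- cache$L_final
  dmat <- dfeat[rep(seq_len(B), each = L), , drop = FALSE] / L
  for (i in rev(seq_len(spec$n_conv_layers))) {
    cc <- cache$caches[[i]]
    if (!is.null(cc$drop_mask)) {
      dmat <- dmat * cc$drop_mask / (1 - spec$dropout_rate)
    }
    dact <- .maxpool_backward(dmat, cc$mp, cc$L_conv, B, spec$channels[i])
    dact <- dact * cc$relu_mask
    bnb <- .bn_backward(dact, cc$bn_cache, params$bn[[i]]$gamma)
    cvb <- .conv_backward(bnb$dx, cc$M, params$conv[[i]]$W,
                          cc$L_in, B, spec$kernel_size, cc$c_in)
    grads$conv[[i]] <- list(W = cvb$dW, b = cvb$db)
    grads$bn[[i]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    dmat <- cvb$dmat
  }
  grads$W1 <- dW1; grads$b1 <- db1; grads$W2 <- dW2; grads$b2 <- db2
  grads
}

# Flatten/unflatten trainable parameters for the Adam update.
.cnn_flatten <- function(params, spec) {
  out <- list()
  for (i in seq_len(spec$n_conv_layers)) {
    out[[length(out) + 1]] <- params$conv[[i]]$W
    out[[length(out) + 1]] <- params$conv[[i]]$b
    out[[length(out) + 1]] <- params$bn[[i]]$gamma
    out[[length(out) + 1]] <- params$bn[[i]]$beta
  }
  out[[length(out) + 1]] <- params$W1
  out[[length(out) + 1]] <- params$b1
  out[[length(out) + 1]] <- params$W2
  out[[length(out) + 1]] <- params$b2
  out
}

.cnn_flatten_grads <- function(grads, spec) {
  out <- list()
  for (i in seq_len(spec$n_conv_layers)) {
    out[[length(out) + 1]] <- grads$conv[[i]]$W
    out[[length(out) + 1]] <- grads$conv[[i]]$b
    out[[length(out) + 1]] <- grads$bn[[i]]$gamma
    out[[length(out) + 1]] <- grads$bn[[i]]$beta
  }
  out[[length(out) + 1]] <- grads$W1
  out[[length(out) + 1]] <- grads$b1
  out[[length(out) + 1]] <- grads$W2
  out[[length(out) + 1]] <- grads$b2
  out
}

.cnn_unflatten <- function(flat, params, spec) {
  j <- 0
  nxt <- function() { j <<- j + 1; flat[[j]] }
  for (i in seq_len(spec$n_conv_layers)) {
    params$conv[[i]]$W <- nxt()
    params$conv[[i]]$b <- nxt()
    params$bn[[i]]$gamma <- nxt()
    params$bn[[i]]$beta <- nxt()
  }
  params$W1 <- nxt(); params$b1 <- nxt()
  params$W2 <- nxt(); params$b2 <- nxt()
  params
}

.adam_state <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0)
}

.adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  for (j in seq_along(flat)) {
    state$m[[j]] <- beta1 * state$m[[j]] + (1 - beta1) * grads[[j]]
    state$v[[j]] <- beta2 * state$v[[j]] + (1 - beta2) * grads[[j]]^2
    mhat <- state$m[[j]] / (1 - beta1^state$t)
    vhat <- state$v[[j]] / (1 - beta2^state$t)
    flat[[j]] <- flat[[j]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}
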