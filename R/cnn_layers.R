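# 1-D CNN building blocks.
#
# Activations travel as 3-D arrays A[batch, length, channels]. The
# convolution and batch-normalization kernels run in compiled code (see
# src/cnn_ops.cpp), where each convolution is k shifted dgemm calls; the
# `_ref` functions below are plain-R reference implementations of the same
# math, kept as an independent check of the compiled path in the tests.

# length-preserving ("same") 1-D convolution, odd kernel
conv1d_fwd <- function(X, W, b) {
  list(out = conv1d_fwd_cpp(X, W, b), X = X)
}

conv1d_bwd <- function(dY, cache, W) {
  conv1d_bwd_cpp(dY, cache$X, W)
}

conv1d_fwd_ref <- function(X, W, b) {
  dm <- dim(X); B <- dm[1]; L <- dm[2]; Cin <- dm[3]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  pad <- (k - 1L) %/% 2L
  Xp <- array(0, c(B, L + k - 1L, Cin))
  Xp[, pad + seq_len(L), ] <- X
  Y <- matrix(rep(b, each = B * L), nrow = B * L)
  for (d in seq_len(k)) {
    Xs <- Xp[, d:(d + L - 1L), , drop = FALSE]
    dim(Xs) <- c(B * L, Cin)
    Y <- Y + Xs %*% matrix(W[d, , ], Cin, Cout)
  }
  dim(Y) <- c(B, L, Cout)
  list(out = Y, X = X)
}

conv1d_bwd_ref <- function(dY, cache, W) {
  X <- cache$X
  dm <- dim(dY); B <- dm[1]; L <- dm[2]; Cout <- dm[3]
  k <- dim(W)[1]; Cin <- dim(W)[2]
  pad <- (k - 1L) %/% 2L
  Xp <- array(0, c(B, L + k - 1L, Cin))
  Xp[, pad + seq_len(L), ] <- X
  dYm <- dY; dim(dYm) <- c(B * L, Cout)
  dW <- array(0, dim(W))
  dXp <- array(0, dim(Xp))
  for (d in seq_len(k)) {
    Xs <- Xp[, d:(d + L - 1L), , drop = FALSE]
    dim(Xs) <- c(B * L, Cin)
    dW[d, , ] <- crossprod(Xs, dYm)
    dXs <- dYm %*% t(matrix(W[d, , ], Cin, Cout))
    dim(dXs) <- c(B, L, Cin)
    dXp[, d:(d + L - 1L), ] <- dXp[, d:(d + L - 1L), , drop = FALSE] + dXs
  }
  list(dX = dXp[, pad + seq_len(L), , drop = FALSE], dW = dW,
       db = colSums(dYm))
}

# batch normalization per channel over (batch, length)
bn_eps <- 1e-5

bn_fwd <- function(X, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1) {
  bn_fwd_cpp(X, gamma, beta, run_mean, run_var, training, momentum, bn_eps)
}

bn_bwd <- function(dY, cache, gamma) {
  bn_bwd_cpp(dY, cache$xhat, cache$inv_sd, gamma)
}

bn_fwd_ref <- function(X, gamma, beta, run_mean, run_var, training,
                       momentum = 0.1) {
  dm <- dim(X)
  Xm <- X; dim(Xm) <- c(dm[1] * dm[2], dm[3])
  if (training) {
    mu <- colMeans(Xm)
    xc <- sweep(Xm, 2, mu)
    v <- colMeans(xc^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
    xc <- sweep(Xm, 2, mu)
  }
  inv_sd <- 1 / sqrt(v + bn_eps)
  xhat <- sweep(xc, 2, inv_sd, `*`)
  Y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(Y) <- dm
  dim(xhat) <- dm
  list(out = Y, xhat = xhat, inv_sd = inv_sd,
       run_mean = run_mean, run_var = run_var)
}

bn_bwd_ref <- function(dY, cache, gamma) {
  dm <- dim(dY); C <- dm[3]
  dYm <- dY; dim(dYm) <- c(dm[1] * dm[2], C)
  xhat <- cache$xhat; dim(xhat) <- dim(dYm)
  N <- nrow(dYm)
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2, gamma, `*`)
  dX <- sweep(N * dxhat, 2, colSums(dxhat)) -
    sweep(xhat, 2, colSums(dxhat * xhat), `*`)
  dX <- sweep(dX, 2, cache$inv_sd / N, `*`)
  dim(dX) <- dm
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(X) {
  mask <- X > 0
  list(out = X * mask, mask = mask)
}

relu_bwd <- function(dY, cache) dY * cache$mask

# max pooling along the length axis, factor 2 (length must be even)
pool2_fwd <- function(X) {
  dm <- dim(X); L <- dm[2]
  odd <- X[, seq(1L, L, by = 2L), , drop = FALSE]
  even <- X[, seq(2L, L, by = 2L), , drop = FALSE]
  take_odd <- odd >= even  # ties go to the earlier sample
  list(out = pmax(odd, even), take_odd = take_odd)
}

pool2_bwd <- function(dY, cache) {
  dm <- dim(dY); B <- dm[1]; Lh <- dm[2]; C <- dm[3]
  dX <- array(0, c(B, 2L * Lh, C))
  dX[, seq(1L, 2L * Lh, by = 2L), ] <- dY * cache$take_odd
  dX[, seq(2L, 2L * Lh, by = 2L), ] <- dY * !cache$take_odd
  dX
}

# global average pooling over the length axis: (B, L, C) -> (B, C)
gap_fwd <- function(X) {
  dm <- dim(X)
  Ap <- aperm(X, c(2, 1, 3))
  dim(Ap) <- c(dm[2], dm[1] * dm[3])
  Y <- colSums(Ap) / dm[2]
  dim(Y) <- c(dm[1], dm[3])
  list(out = Y, L = dm[2])
}

gap_bwd <- function(dY, cache) {
  B <- nrow(dY); C <- ncol(dY); L <- cache$L
  # broadcast dY/L over the length axis
  aperm(array(t(dY / L), c(C, B, L)), c(2, 3, 1))
}

dense_fwd <- function(X, W, b) {
  list(out = X %*% W + b, X = X)
}

dense_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

# Adam update over a flat named list of parameter arrays
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}
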