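# Minimal sequence-labeling network engine: 1-D convolution, batch/layer
# normalization, max-pooling, nearest-neighbour upsampling, multi-head
# self-attention and bidirectional LSTM/GRU (time loops in C++), with
# hand-derived backward passes and Adam. Batches are (B, T, C) arrays:
# B segments, T timepoints, C channels. All matmuls go through BLAS.

.as_btc <- function(x) {
  # promote a (B, T) matrix to a single-channel (B, T, 1) batch
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

.glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  s <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -s, s), dims)
}

# ---- convolution (same padding, optional fused ReLU) -----------------------

.conv_fwd <- function(X, W, b, act = c("linear", "relu")) {
  act <- match.arg(act)
  d <- dim(X); B <- d[1]; Tn <- d[2]; C <- d[3]
  k <- nrow(W) / C
  left <- (k - 1) %/% 2
  Xp <- array(0, c(B, Tn + k - 1L, C))
  Xp[, left + seq_len(Tn), ] <- X
  patches <- matrix(0, B * Tn, k * C)
  for (dd in seq_len(k)) {
    sl <- Xp[, dd:(dd + Tn - 1L), , drop = FALSE]
    dim(sl) <- c(B * Tn, C)
    patches[, ((dd - 1L) * C + 1L):(dd * C)] <- sl
  }
  Z <- patches %*% W
  Z <- sweep(Z, 2L, b, `+`)
  mask <- NULL
  if (act == "relu") {
    mask <- Z > 0
    Z[!mask] <- 0
  }
  Y <- Z
  dim(Y) <- c(B, Tn, ncol(W))
  list(out = Y, cache = list(patches = patches, mask = mask, dims = d,
                             k = k, left = left))
}

.conv_bwd <- function(dY, W, cache) {
  d <- cache$dims; B <- d[1]; Tn <- d[2]; C <- d[3]
  Fo <- ncol(W); k <- cache$k; left <- cache$left
  dZ <- dY
  dim(dZ) <- c(B * Tn, Fo)
  if (!is.null(cache$mask)) dZ <- dZ * cache$mask
  dW <- crossprod(cache$patches, dZ)
  db <- colSums(dZ)
  dP <- tcrossprod(dZ, W) # (B*Tn, k*C)
  dXp <- array(0, c(B, Tn + k - 1L, C))
  for (dd in seq_len(k)) {
    blk <- dP[, ((dd - 1L) * C + 1L):(dd * C), drop = FALSE]
    dim(blk) <- c(B, Tn, C)
    dXp[, dd:(dd + Tn - 1L), ] <- dXp[, dd:(dd + Tn - 1L), , drop = FALSE] + blk
  }
  dX <- dXp[, left + seq_len(Tn), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# ---- batch normalization (per channel over batch x time) -------------------

.bn_fwd <- function(X, gamma, beta, running, train, momentum = 0.9,
                    eps = 1e-5) {
  d <- dim(X); B <- d[1]; Tn <- d[2]; C <- d[3]
  Xm <- X; dim(Xm) <- c(B * Tn, C)
  if (train) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm^2) - mu^2
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  sdv <- sqrt(v + eps)
  xhat <- sweep(sweep(Xm, 2L, mu, `-`), 2L, sdv, `/`)
  Y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  dim(Y) <- d
  list(out = Y, cache = list(xhat = xhat, sdv = sdv, dims = d),
       running = running)
}

.bn_bwd <- function(dY, gamma, cache) {
  d <- cache$dims; N <- d[1] * d[2]; C <- d[3]
  dYm <- dY; dim(dYm) <- c(N, C)
  xhat <- cache$xhat
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2L, gamma, `*`)
  dX <- sweep(dxhat, 2L, colMeans(dxhat), `-`) -
    xhat * matrix(colMeans(dxhat * xhat), N, C, byrow = TRUE)
  dX <- sweep(dX, 2L, cache$sdv, `/`)
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- layer normalization (per timepoint over channels) ---------------------

.ln_fwd <- function(X, gamma, beta, eps = 1e-5) {
  d <- dim(X); N <- d[1] * d[2]; C <- d[3]
  Xm <- X; dim(Xm) <- c(N, C)
  mu <- rowMeans(Xm)
  v <- rowMeans(Xm^2) - mu^2
  sdv <- sqrt(v + eps)
  xhat <- (Xm - mu) / sdv
  Y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  dim(Y) <- d
  list(out = Y, cache = list(xhat = xhat, sdv = sdv, dims = d))
}

.ln_bwd <- function(dY, gamma, cache) {
  d <- cache$dims; N <- d[1] * d[2]; C <- d[3]
  dYm <- dY; dim(dYm) <- c(N, C)
  xhat <- cache$xhat
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2L, gamma, `*`)
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sdv
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- max pooling / upsampling ----------------------------------------------

.pool_fwd <- function(X, p) {
  d <- dim(X); B <- d[1]; Tn <- d[2]; C <- d[3]
  stopifnot(Tn %% p == 0L)
  Y <- X[, seq.int(1L, Tn, by = p), , drop = FALSE]
  arg <- array(1L, dim(Y))
  if (p > 1L) {
    for (dd in 2:p) {
      Xd <- X[, seq.int(dd, Tn, by = p), , drop = FALSE]
      upd <- Xd > Y
      Y[upd] <- Xd[upd]
      arg[upd] <- dd
    }
  }
  list(out = Y, cache = list(arg = arg, dims = d, p = p))
}

.pool_bwd <- function(dY, cache) {
  d <- cache$dims; p <- cache$p
  dX <- array(0, d)
  for (dd in seq_len(p)) {
    blk <- dY
    blk[cache$arg != dd] <- 0
    dX[, seq.int(dd, d[2], by = p), ] <- blk
  }
  dX
}

.up_fwd <- function(X, u) {
  d <- dim(X)
  Y <- array(0, c(d[1], d[2] * u, d[3]))
  for (dd in seq_len(u)) Y[, seq.int(dd, d[2] * u, by = u), ] <- X
  list(out = Y, cache = list(u = u))
}

.up_bwd <- function(dY, cache) {
  u <- cache$u
  Tn <- dim(dY)[2] / u
  dX <- dY[, seq.int(1L, dim(dY)[2], by = u), , drop = FALSE]
  if (u > 1L) {
    for (dd in 2:u) {
      dX <- dX + dY[, seq.int(dd, dim(dY)[2], by = u), , drop = FALSE]
    }
  }
  dX
}

# ---- time padding to a pooling-compatible length ---------------------------

.pad_time <- function(X, multiple) {
  d <- dim(X); Tn <- d[2]
  Tp <- as.integer(ceiling(Tn / multiple) * multiple)
  if (Tp == Tn) return(list(out = X, left = 0L, t_orig = Tn))
  left <- (Tp - Tn) %/% 2L
  Y <- array(0, c(d[1], Tp, d[3]))
  Y[, left + seq_len(Tn), ] <- X
  list(out = Y, left = left, t_orig = Tn)
}

.crop_time <- function(X, left, t_orig) {
  X[, left + seq_len(t_orig), , drop = FALSE]
}

.pad_grad <- function(dX_cropped, d_padded, left, t_orig) {
  dX <- array(0, d_padded)
  dX[, left + seq_len(t_orig), ] <- dX_cropped
  dX
}

# ---- multi-head self-attention ---------------------------------------------

.mha_fwd <- function(X, Wq, Wk, Wv, Wo, heads) {
  d <- dim(X); B <- d[1]; Tn <- d[2]; C <- d[3]
  dk <- C %/% heads
  Y <- array(0, d)
  Qs <- Ks <- Vs <- vector("list", B)
  for (b in seq_len(B)) {
    Xb <- matrix(X[b, , ], Tn, C)
    Q <- Xb %*% Wq; K <- Xb %*% Wk; V <- Xb %*% Wv
    O <- matrix(0, Tn, C)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dk)
      S <- sweep(S, 1L, apply(S, 1L, max), `-`)
      A <- exp(S)
      A <- A / rowSums(A)
      O[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    Y[b, , ] <- O %*% Wo
    Qs[[b]] <- Q; Ks[[b]] <- K; Vs[[b]] <- V
  }
  list(out = Y, cache = list(Q = Qs, K = Ks, V = Vs, X = X, heads = heads))
}

.mha_bwd <- function(dY, Wq, Wk, Wv, Wo, cache) {
  X <- cache$X
  d <- dim(X); B <- d[1]; Tn <- d[2]; C <- d[3]
  heads <- cache$heads; dk <- C %/% heads
  dX <- array(0, d)
  dWq <- dWk <- dWv <- dWo <- matrix(0, C, C)
  for (b in seq_len(B)) {
    Xb <- matrix(X[b, , ], Tn, C)
    Q <- cache$Q[[b]]; K <- cache$K[[b]]; V <- cache$V[[b]]
    dYb <- matrix(dY[b, , ], Tn, C)
    # recompute head outputs for dWo
    O <- matrix(0, Tn, C)
    dO <- tcrossprod(dYb, Wo) # dYb %*% t(Wo)
    dQ <- dK <- dV <- matrix(0, Tn, C)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dk)
      S <- sweep(S, 1L, apply(S, 1L, max), `-`)
      A <- exp(S); A <- A / rowSums(A)
      O[, cols] <- A %*% V[, cols, drop = FALSE]
      dOh <- dO[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- dS %*% K[, cols, drop = FALSE] / sqrt(dk)
      dK[, cols] <- crossprod(dS, Q[, cols, drop = FALSE]) / sqrt(dk)
    }
    dWo <- dWo + crossprod(O, dYb)
    dWq <- dWq + crossprod(Xb, dQ)
    dWk <- dWk + crossprod(Xb, dK)
    dWv <- dWv + crossprod(Xb, dV)
    dX[b, , ] <- tcrossprod(dQ, Wq) + tcrossprod(dK, Wk) + tcrossprod(dV, Wv)
  }
  list(dX = dX, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

# ---- bidirectional recurrent wrappers --------------------------------------
# These operate on (B, C, T) cubes so stacked layers chain without any
# layout shuffling; the time reversal of the backward direction happens
# inside the C++ kernels.

.bdir_fwd <- function(Xc, pars, cell = c("lstm", "gru")) {
  cell <- match.arg(cell)
  run <- function(p, rev) {
    if (cell == "lstm") {
      .lstm_forward_cpp(Xc, p$W, p$U, p$b, rev)
    } else {
      .gru_forward_cpp(Xc, p$W, p$U, p$b, rev)
    }
  }
  ff <- run(pars$f, FALSE)
  bb <- run(pars$b, TRUE)
  H <- dim(ff$H)[2]
  d <- dim(Xc)
  Y <- array(0, c(d[1], 2L * H, d[3]))
  Y[, seq_len(H), ] <- ff$H
  Y[, H + seq_len(H), ] <- bb$H
  list(out = Y, cache = list(ff = ff, bb = bb, Xc = Xc, H = H, cell = cell))
}

.bdir_bwd <- function(dY, pars, cache) {
  H <- cache$H; cell <- cache$cell
  dHf <- dY[, seq_len(H), , drop = FALSE]
  dHb <- dY[, H + seq_len(H), , drop = FALSE]
  back <- function(dH, st, p, rev) {
    if (cell == "lstm") {
      .lstm_backward_cpp(cache$Xc, dH, st$H, st$C, st$G, p$W, p$U, rev)
    } else {
      .gru_backward_cpp(cache$Xc, dH, st$H, st$G, st$HU, p$W, p$U, rev)
    }
  }
  gf <- back(dHf, cache$ff, pars$f, FALSE)
  gb <- back(dHb, cache$bb, pars$b, TRUE)
  list(dX = gf$dX + gb$dX,
       grads = list(f = list(W = gf$dW, U = gf$dU, b = as.numeric(gf$db)),
                    b = list(W = gb$dW, U = gb$dU, b = as.numeric(gb$db))))
}

.init_rnn <- function(C, H, cell = c("lstm", "gru")) {
  cell <- match.arg(cell)
  ng <- if (cell == "lstm") 4L else 3L
  one_dir <- function() {
    b <- numeric(ng * H)
    if (cell == "lstm") b[(H + 1L):(2L * H)] <- 1 # forget-gate bias
    list(W = .glorot(C, ng * H), U = .glorot(H, ng * H), b = b)
  }
  list(f = one_dir(), b = one_dir())
}

# ---- loss -------------------------------------------------------------------

# Per-sample binary cross-entropy on logits; returns mean loss and gradient.
.bce_with_logits <- function(Z, Y) {
  n <- length(Z)
  loss <- sum(pmax(Z, 0) - Z * Y + log1p(exp(-abs(Z)))) / n
  probs <- stats::plogis(Z)
  list(loss = loss, dZ = (probs - Y) / n, probs = probs)
}

.grad_sq_sum <- function(g) {
  if (is.list(g)) sum(vapply(g, .grad_sq_sum, 0)) else sum(g^2)
}

.grad_scale <- function(g, s) {
  if (is.list(g)) lapply(g, .grad_scale, s = s) else g * s
}

# ---- Adam -------------------------------------------------------------------

.zeros_like <- function(p) {
  if (is.list(p)) lapply(p, .zeros_like) else array(0, dim(p) %||% length(p))
}

.adam_init <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

.adam_walk <- function(p, g, m, v, lr, b1, b2, eps, bc1, bc2) {
  if (is.list(p)) {
    out <- Map(.adam_walk, p, g, m, v,
               MoreArgs = list(lr = lr, b1 = b1, b2 = b2, eps = eps,
                               bc1 = bc1, bc2 = bc2))
    list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
         v = lapply(out, `[[`, "v"))
  } else {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
}

.adam_step <- function(params, grads, opt, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  res <- .adam_walk(params, grads, opt$m, opt$v, lr, b1, b2, eps,
                    bc1 = 1 - b1^opt$t, bc2 = 1 - b2^opt$t)
  opt$m <- res$m
  opt$v <- res$v
  list(params = res$p, opt = opt)
}
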