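# Family-specific network graphs built from the engine primitives. Each
# family provides: parameter initialization, a forward pass producing
# per-sample logits, and a backward pass producing gradients congruent with
# the parameter list. Input is a (B, T) matrix of standardized amplitudes.

.relu_op_fwd <- function(X) {
  mask <- X > 0
  X[!mask] <- 0
  list(out = X, cache = mask)
}

.relu_op_bwd <- function(dY, mask) {
  dY[!mask] <- 0
  dY
}

.cat_ch <- function(A, B) {
  da <- dim(A); db <- dim(B)
  Y <- array(0, c(da[1], da[2], da[3] + db[3]))
  Y[, , seq_len(da[3])] <- A
  Y[, , da[3] + seq_len(db[3])] <- B
  Y
}

.split_ch <- function(dY, ca) {
  list(dA = dY[, , seq_len(ca), drop = FALSE],
       dB = dY[, , -seq_len(ca), drop = FALSE])
}

.scale_width <- function(w, scale) pmax(4L, as.integer(round(w * scale)))

# ---- build ------------------------------------------------------------------

.net_build <- function(spec, input_length) {
  fam <- spec$family
  ws <- spec$width_scale
  cfg <- switch(fam,
    cnn1d = list(filters = .scale_width(c(64L, 128L), ws),
                 kernels = c(7L, 3L), pool = 2L, pad = 4L),
    transformer = list(filters = .scale_width(64L, ws), kernel = 3L,
                       heads = spec$heads, pad = 1L),
    unet = list(filters = .scale_width(c(64L, 128L, 256L), ws), kernel = 3L,
                pad = 8L),
    cnn_gru = ,
    cnn_lstm = list(filters = .scale_width(c(64L, 128L), ws),
                    kernels = c(5L, 3L),
                    units = .scale_width(c(200L, 100L, 50L), ws),
                    pool = 2L, pad = 4L, l2 = spec$l2),
    abort(sprintf("Unknown detector family '%s'.", fam)))
  if (input_length < 4L * cfg$pad) {
    abort(sprintf("Input length %d too short for family '%s'.",
                  input_length, fam))
  }
  conv_par <- function(k, cin, cout) {
    list(W = .glorot(k * cin, cout, c(k * cin, cout)), b = numeric(cout))
  }
  if (fam == "cnn1d") {
    f <- cfg$filters
    params <- list(conv1 = conv_par(cfg$kernels[1], 1L, f[1]),
                   conv2 = conv_par(cfg$kernels[2], f[1], f[2]),
                   head = conv_par(1L, f[2], 1L))
    state <- list()
  } else if (fam == "transformer") {
    f <- cfg$filters
    if (f %% cfg$heads != 0L) {
      abort("Transformer width must be divisible by the number of heads.")
    }
    params <- list(conv1 = conv_par(cfg$kernel, 1L, f),
                   ln1 = list(gamma = rep(1, f), beta = numeric(f)),
                   mha = list(Wq = .glorot(f, f), Wk = .glorot(f, f),
                              Wv = .glorot(f, f), Wo = .glorot(f, f)),
                   ln2 = list(gamma = rep(1, f), beta = numeric(f)),
                   head = conv_par(1L, f, 1L))
    state <- list()
  } else if (fam == "unet") {
    f <- cfg$filters; k <- cfg$kernel
    params <- list(enc1 = conv_par(k, 1L, f[1]),
                   enc2 = conv_par(k, f[1], f[2]),
                   enc3 = conv_par(k, f[2], f[3]),
                   bott = conv_par(k, f[3], f[3]),
                   dec3 = conv_par(k, f[3] + f[3], f[2]),
                   dec2 = conv_par(k, f[2] + f[2], f[1]),
                   dec1 = conv_par(k, f[1] + f[1], f[1]),
                   head = conv_par(1L, f[1], 1L))
    state <- list()
  } else { # cnn_gru / cnn_lstm
    f <- cfg$filters; u <- cfg$units
    cell <- if (fam == "cnn_lstm") "lstm" else "gru"
    params <- list(conv1 = conv_par(cfg$kernels[1], 1L, f[1]),
                   bn1 = list(gamma = rep(1, f[1]), beta = numeric(f[1])),
                   conv2 = conv_par(cfg$kernels[2], f[1], f[2]),
                   bn2 = list(gamma = rep(1, f[2]), beta = numeric(f[2])),
                   rnn1 = .init_rnn(f[2], u[1], cell),
                   rnn2 = .init_rnn(2L * u[1], u[2], cell),
                   rnn3 = .init_rnn(2L * u[2], u[3], cell),
                   head = conv_par(1L, 2L * u[3], 1L))
    state <- list(bn1 = list(mean = numeric(f[1]), var = rep(1, f[1])),
                  bn2 = list(mean = numeric(f[2]), var = rep(1, f[2])))
  }
  list(family = fam, config = cfg, params = params, state = state,
       input_length = as.integer(input_length))
}

# ---- forward / backward -----------------------------------------------------

.net_forward <- function(net, Xin, train = FALSE) {
  p <- net$params; cfg <- net$config; fam <- net$family
  X <- .as_btc(Xin)
  pd <- .pad_time(X, cfg$pad)
  X <- pd$out
  cache <- list(pad = pd, dim_padded = dim(X))
  state <- net$state
  if (fam == "cnn1d") {
    c1 <- .conv_fwd(X, p$conv1$W, p$conv1$b, "relu")
    p1 <- .pool_fwd(c1$out, cfg$pool)
    c2 <- .conv_fwd(p1$out, p$conv2$W, p$conv2$b, "relu")
    p2 <- .pool_fwd(c2$out, cfg$pool)
    up <- .up_fwd(p2$out, cfg$pool^2)
    hd <- .conv_fwd(up$out, p$head$W, p$head$b, "linear")
    cache <- c(cache, list(c1 = c1, p1 = p1, c2 = c2, p2 = p2, up = up,
                           hd = hd))
    out <- hd$out
  } else if (fam == "transformer") {
    c1 <- .conv_fwd(X, p$conv1$W, p$conv1$b, "relu")
    l1 <- .ln_fwd(c1$out, p$ln1$gamma, p$ln1$beta)
    at <- .mha_fwd(l1$out, p$mha$Wq, p$mha$Wk, p$mha$Wv, p$mha$Wo, cfg$heads)
    res <- c1$out + at$out
    l2 <- .ln_fwd(res, p$ln2$gamma, p$ln2$beta)
    hd <- .conv_fwd(l2$out, p$head$W, p$head$b, "linear")
    cache <- c(cache, list(c1 = c1, l1 = l1, at = at, l2 = l2, hd = hd))
    out <- hd$out
  } else if (fam == "unet") {
    e1 <- .conv_fwd(X, p$enc1$W, p$enc1$b, "relu")
    p1 <- .pool_fwd(e1$out, 2L)
    e2 <- .conv_fwd(p1$out, p$enc2$W, p$enc2$b, "relu")
    p2 <- .pool_fwd(e2$out, 2L)
    e3 <- .conv_fwd(p2$out, p$enc3$W, p$enc3$b, "relu")
    p3 <- .pool_fwd(e3$out, 2L)
    bo <- .conv_fwd(p3$out, p$bott$W, p$bott$b, "relu")
    u3 <- .up_fwd(bo$out, 2L)
    d3 <- .conv_fwd(.cat_ch(u3$out, e3$out), p$dec3$W, p$dec3$b, "relu")
    u2 <- .up_fwd(d3$out, 2L)
    d2 <- .conv_fwd(.cat_ch(u2$out, e2$out), p$dec2$W, p$dec2$b, "relu")
    u1 <- .up_fwd(d2$out, 2L)
    d1 <- .conv_fwd(.cat_ch(u1$out, e1$out), p$dec1$W, p$dec1$b, "relu")
    hd <- .conv_fwd(d1$out, p$head$W, p$head$b, "linear")
    cache <- c(cache, list(e1 = e1, p1 = p1, e2 = e2, p2 = p2, e3 = e3,
                           p3 = p3, bo = bo, u3 = u3, d3 = d3, u2 = u2,
                           d2 = d2, u1 = u1, d1 = d1, hd = hd))
    out <- hd$out
  } else { # cnn_gru / cnn_lstm
    cell <- if (fam == "cnn_lstm") "lstm" else "gru"
    c1 <- .conv_fwd(X, p$conv1$W, p$conv1$b, "linear")
    b1 <- .bn_fwd(c1$out, p$bn1$gamma, p$bn1$beta, state$bn1, train)
    state$bn1 <- b1$running
    r1 <- .relu_op_fwd(b1$out)
    p1 <- .pool_fwd(r1$out, cfg$pool)
    c2 <- .conv_fwd(p1$out, p$conv2$W, p$conv2$b, "linear")
    b2 <- .bn_fwd(c2$out, p$bn2$gamma, p$bn2$beta, state$bn2, train)
    state$bn2 <- b2$running
    r2 <- .relu_op_fwd(b2$out)
    p2 <- .pool_fwd(r2$out, cfg$pool)
    Xc <- aperm(p2$out, c(1L, 3L, 2L)) # (B, C, T) for the recurrent stack
    h1 <- .bdir_fwd(Xc, p$rnn1, cell)
    h2 <- .bdir_fwd(h1$out, p$rnn2, cell)
    h3 <- .bdir_fwd(h2$out, p$rnn3, cell)
    up <- .up_fwd(aperm(h3$out, c(1L, 3L, 2L)), cfg$pool^2)
    hd <- .conv_fwd(up$out, p$head$W, p$head$b, "linear")
    cache <- c(cache, list(c1 = c1, b1 = b1, r1 = r1, p1 = p1, c2 = c2,
                           b2 = b2, r2 = r2, p2 = p2, h1 = h1, h2 = h2,
                           h3 = h3, up = up, hd = hd))
    out <- hd$out
  }
  logits <- .crop_time(out, pd$left, pd$t_orig)
  dim(logits) <- dim(logits)[1:2]
  list(logits = logits, cache = cache, state = state)
}

.net_backward <- function(net, cache, dlogits) {
  p <- net$params; cfg <- net$config; fam <- net$family
  dZ <- .pad_grad(.as_btc(dlogits),
                  c(dim(dlogits)[1], cache$dim_padded[2], 1L),
                  cache$pad$left, cache$pad$t_orig)
  # dZ has the padded time length and 1 channel
  if (fam == "cnn1d") {
    g_hd <- .conv_bwd(dZ, p$head$W, cache$hd$cache)
    d_up <- .up_bwd(g_hd$dX, cache$up$cache)
    d_p2 <- .pool_bwd(d_up, cache$p2$cache)
    g_c2 <- .conv_bwd(d_p2, p$conv2$W, cache$c2$cache)
    d_p1 <- .pool_bwd(g_c2$dX, cache$p1$cache)
    g_c1 <- .conv_bwd(d_p1, p$conv1$W, cache$c1$cache)
    list(conv1 = list(W = g_c1$dW, b = g_c1$db),
         conv2 = list(W = g_c2$dW, b = g_c2$db),
         head = list(W = g_hd$dW, b = g_hd$db))
  } else if (fam == "transformer") {
    g_hd <- .conv_bwd(dZ, p$head$W, cache$hd$cache)
    g_l2 <- .ln_bwd(g_hd$dX, p$ln2$gamma, cache$l2$cache)
    d_res <- g_l2$dX
    g_at <- .mha_bwd(d_res, p$mha$Wq, p$mha$Wk, p$mha$Wv, p$mha$Wo,
                     cache$at$cache)
    g_l1 <- .ln_bwd(g_at$dX, p$ln1$gamma, cache$l1$cache)
    d_c1 <- d_res + g_l1$dX # residual path + attention path
    g_c1 <- .conv_bwd(d_c1, p$conv1$W, cache$c1$cache)
    list(conv1 = list(W = g_c1$dW, b = g_c1$db),
         ln1 = list(gamma = g_l1$dgamma, beta = g_l1$dbeta),
         mha = list(Wq = g_at$dWq, Wk = g_at$dWk, Wv = g_at$dWv,
                    Wo = g_at$dWo),
         ln2 = list(gamma = g_l2$dgamma, beta = g_l2$dbeta),
         head = list(W = g_hd$dW, b = g_hd$db))
  } else if (fam == "unet") {
    f <- cfg$filters
    g_hd <- .conv_bwd(dZ, p$head$W, cache$hd$cache)
    g_d1 <- .conv_bwd(g_hd$dX, p$dec1$W, cache$d1$cache)
    s1 <- .split_ch(g_d1$dX, f[1])
    d_u1 <- .up_bwd(s1$dA, cache$u1$cache)
    g_d2 <- .conv_bwd(d_u1, p$dec2$W, cache$d2$cache)
    s2 <- .split_ch(g_d2$dX, f[2])
    d_u2 <- .up_bwd(s2$dA, cache$u2$cache)
    g_d3 <- .conv_bwd(d_u2, p$dec3$W, cache$d3$cache)
    s3 <- .split_ch(g_d3$dX, f[3])
    d_u3 <- .up_bwd(s3$dA, cache$u3$cache)
    g_bo <- .conv_bwd(d_u3, p$bott$W, cache$bo$cache)
    d_p3 <- .pool_bwd(g_bo$dX, cache$p3$cache)
    g_e3 <- .conv_bwd(d_p3 + s3$dB, p$enc3$W, cache$e3$cache)
    d_p2 <- .pool_bwd(g_e3$dX, cache$p2$cache)
    g_e2 <- .conv_bwd(d_p2 + s2$dB, p$enc2$W, cache$e2$cache)
    d_p1 <- .pool_bwd(g_e2$dX, cache$p1$cache)
    g_e1 <- .conv_bwd(d_p1 + s1$dB, p$enc1$W, cache$e1$cache)
    list(enc1 = list(W = g_e1$dW, b = g_e1$db),
         enc2 = list(W = g_e2$dW, b = g_e2$db),
         enc3 = list(W = g_e3$dW, b = g_e3$db),
         bott = list(W = g_bo$dW, b = g_bo$db),
         dec3 = list(W = g_d3$dW, b = g_d3$db),
         dec2 = list(W = g_d2$dW, b = g_d2$db),
         dec1 = list(W = g_d1$dW, b = g_d1$db),
         head = list(W = g_hd$dW, b = g_hd$db))
  } else { # cnn_gru / cnn_lstm
    g_hd <- .conv_bwd(dZ, p$head$W, cache$hd$cache)
    d_up <- .up_bwd(g_hd$dX, cache$up$cache)
    g_h3 <- .bdir_bwd(aperm(d_up, c(1L, 3L, 2L)), p$rnn3, cache$h3$cache)
    g_h2 <- .bdir_bwd(g_h3$dX, p$rnn2, cache$h2$cache)
    g_h1 <- .bdir_bwd(g_h2$dX, p$rnn1, cache$h1$cache)
    d_p2 <- .pool_bwd(aperm(g_h1$dX, c(1L, 3L, 2L)), cache$p2$cache)
    d_r2 <- .relu_op_bwd(d_p2, cache$r2$cache)
    g_b2 <- .bn_bwd(d_r2, p$bn2$gamma, cache$b2$cache)
    g_c2 <- .conv_bwd(g_b2$dX, p$conv2$W, cache$c2$cache)
    d_p1 <- .pool_bwd(g_c2$dX, cache$p1$cache)
    d_r1 <- .relu_op_bwd(d_p1, cache$r1$cache)
    g_b1 <- .bn_bwd(d_r1, p$bn1$gamma, cache$b1$cache)
    g_c1 <- .conv_bwd(g_b1$dX, p$conv1$W, cache$c1$cache)
    list(conv1 = list(W = g_c1$dW, b = g_c1$db),
         bn1 = list(gamma = g_b1$dgamma, beta = g_b1$dbeta),
         conv2 = list(W = g_c2$dW, b = g_c2$db),
         bn2 = list(gamma = g_b2$dgamma, beta = g_b2$dbeta),
         rnn1 = g_h1$grads, rnn2 = g_h2$grads, rnn3 = g_h3$grads,
         head = list(W = g_hd$dW, b = g_hd$db))
  }
}
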