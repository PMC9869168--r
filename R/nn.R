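# Minimal dense/conv/recurrent neural-network kernels in base R matrix code.
# Feature maps are stored column-per-sample: a [C, H, W] map is flattened
# column-major to a [C*H*W, B] matrix (channel fastest, then height, then
# width). All layers implement forward + backward pairs; gradients are
# checked against numerical differentiation in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- convolution (same padding) --------------------------------------------

# Precompute the im2col gather index for a [C, H, W] input with a kh x kw
# kernel and zero padding `pad`. Index values address the flattened padded
# array [C, H+2p, W+2p]; row order is channel fastest, then kernel row,
# then kernel column; column order is output position (h fastest).
conv_index <- function(C, H, W, kh, kw, pad) {
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  kidx <- as.matrix(expand.grid(c = seq_len(C), dh = 0L:(kh - 1L),
                                dw = 0L:(kw - 1L)))
  pos <- as.matrix(expand.grid(h = seq_len(H), w = seq_len(W)))
  idx <- matrix(0L, nrow(kidx), nrow(pos))
  for (j in seq_len(nrow(pos))) {
    hh <- pos[j, 1L] + kidx[, 2L]          # 1-based row in padded map
    ww <- pos[j, 2L] + kidx[, 3L]
    idx[, j] <- kidx[, 1L] + C * (hh - 1L) + C * Hp * (ww - 1L)
  }
  list(idx = idx, C = C, H = H, W = W, Hp = Hp, Wp = Wp, pad = pad,
       K = nrow(kidx), n_pos = nrow(pos))
}

pad_maps <- function(X, ci) {
  if (ci$pad == 0L) return(X)
  B <- ncol(X)
  Xp <- matrix(0, ci$C * ci$Hp * ci$Wp, B)
  inner <- inner_index(ci)
  Xp[inner, ] <- X
  Xp
}

inner_index <- function(ci) {
  # flat indices of the unpadded region inside the padded map
  g <- expand.grid(c = seq_len(ci$C), h = seq_len(ci$H) + ci$pad,
                   w = seq_len(ci$W) + ci$pad)
  g$c + ci$C * (g$h - 1L) + ci$C * ci$Hp * (g$w - 1L)
}

conv_forward <- function(X, Wm, b, ci) {
  B <- ncol(X)
  Xp <- pad_maps(X, ci)
  P <- Xp[as.vector(ci$idx), , drop = FALSE]
  dim(P) <- c(ci$K, ci$n_pos * B)
  Y <- Wm %*% P + b
  dim(Y) <- c(nrow(Wm) * ci$n_pos, B)
  list(out = Y, P = P, B = B)
}

conv_backward <- function(dY, Wm, ci, cache) {
  B <- cache$B
  Cout <- nrow(Wm)
  dim(dY) <- c(Cout, ci$n_pos * B)
  dW <- dY %*% t(cache$P)
  db <- rowSums(dY)
  dP <- t(Wm) %*% dY
  dim(dP) <- c(ci$K * ci$n_pos, B)
  grp <- as.vector(ci$idx)
  agg <- rowsum(dP, grp)                    # rows sorted by unique index
  dXp <- matrix(0, ci$C * ci$Hp * ci$Wp, B)
  dXp[as.integer(rownames(agg)), ] <- agg
  dX <- if (ci$pad > 0L) dXp[inner_index(ci), , drop = FALSE] else dXp
  list(dX = dX, dW = dW, db = db)
}

# --- batch normalization (per channel) --------------------------------------

bn_forward <- function(X, gamma, beta, run_mean, run_var, C, training,
                       momentum = 0.1, eps = 1e-5) {
  B <- ncol(X)
  n_pos <- nrow(X) / C
  Xc <- matrix(X, nrow = C)                 # channel fastest: [C, pos*B]
  if (training) {
    mu <- rowMeans(Xc)
    v <- rowMeans((Xc - mu)^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  Xhat <- (Xc - mu) * inv_sd
  Y <- gamma * Xhat + beta
  dim(Y) <- dim(X)
  list(out = Y, xhat = Xhat, inv_sd = inv_sd, run_mean = run_mean,
       run_var = run_var, C = C, m = ncol(Xc))
}

bn_backward <- function(dY, gamma, cache) {
  C <- cache$C
  dYc <- matrix(dY, nrow = C)
  m <- cache$m
  dgamma <- rowSums(dYc * cache$xhat)
  dbeta <- rowSums(dYc)
  dxhat <- gamma * dYc
  dX <- (cache$inv_sd / m) *
    (m * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  dim(dX) <- dim(dY)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# --- 2D max pooling ---------------------------------------------------------

# Index table for ph x pw pooling of a [C, H, W] map (floor semantics:
# trailing rows/columns that do not fill a window are dropped).
pool_index <- function(C, H, W, ph, pw) {
  Ho <- H %/% ph
  Wo <- W %/% pw
  if (Ho < 1L || Wo < 1L) stop("pooling window larger than input")
  out_pos <- expand.grid(c = seq_len(C), h = seq_len(Ho), w = seq_len(Wo))
  m <- ph * pw
  idx <- matrix(0L, m, nrow(out_pos))
  k <- 0L
  for (dw in 0L:(pw - 1L)) for (dh in 0L:(ph - 1L)) {
    k <- k + 1L
    hh <- (out_pos$h - 1L) * ph + 1L + dh
    ww <- (out_pos$w - 1L) * pw + 1L + dw
    idx[k, ] <- out_pos$c + C * (hh - 1L) + C * H * (ww - 1L)
  }
  list(idx = idx, C = C, Ho = Ho, Wo = Wo, n_in = C * H * W, m = m)
}

pool_forward <- function(X, pi_) {
  B <- ncol(X)
  n_out <- ncol(pi_$idx)
  Y <- X[pi_$idx[1L, ], , drop = FALSE]
  am <- matrix(1L, n_out, B)
  for (k in 2L:pi_$m) {
    Ak <- X[pi_$idx[k, ], , drop = FALSE]
    upd <- Ak > Y
    Y[upd] <- Ak[upd]
    am[upd] <- k
  }
  list(out = Y, argmax = am, B = B)
}

pool_backward <- function(dY, pi_, cache) {
  B <- cache$B
  n_out <- ncol(pi_$idx)
  dX <- matrix(0, pi_$n_in, B)
  rows <- pi_$idx[cbind(as.vector(cache$argmax),
                        rep(seq_len(n_out), B))]
  lin <- rows + (rep(seq_len(B), each = n_out) - 1L) * pi_$n_in
  dX[lin] <- as.vector(dY)
  dX
}

# --- GRU --------------------------------------------------------------------

gru_init <- function(D, U, rng_sd) {
  list(Wz = matrix(stats::rnorm(U * D, sd = rng_sd), U, D),
       Wr = matrix(stats::rnorm(U * D, sd = rng_sd), U, D),
       Wn = matrix(stats::rnorm(U * D, sd = rng_sd), U, D),
       Uz = matrix(stats::rnorm(U * U, sd = rng_sd), U, U),
       Ur = matrix(stats::rnorm(U * U, sd = rng_sd), U, U),
       Un = matrix(stats::rnorm(U * U, sd = rng_sd), U, U),
       bz = numeric(U), br = numeric(U), bn = numeric(U))
}

# One direction over a list of [D, B] inputs; returns per-step hidden states.
gru_forward <- function(S, p) {
  T_ <- length(S)
  B <- ncol(S[[1L]])
  U <- nrow(p$Wz)
  h <- matrix(0, U, B)
  hs <- vector("list", T_)
  cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    x <- S[[t]]
    z <- sigmoid(p$Wz %*% x + p$Uz %*% h + p$bz)
    r <- sigmoid(p$Wr %*% x + p$Ur %*% h + p$br)
    unh <- p$Un %*% h
    n <- tanh(p$Wn %*% x + r * unh + p$bn)
    h_new <- (1 - z) * n + z * h
    cache[[t]] <- list(x = x, h_prev = h, z = z, r = r, n = n, unh = unh)
    h <- h_new
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

gru_backward <- function(dhs, p, cache) {
  T_ <- length(dhs)
  g <- lapply(p, function(w) w * 0)
  dh_next <- dhs[[T_]] * 0
  dX <- vector("list", T_)
  for (t in rev(seq_len(T_))) {
    cc <- cache[[t]]
    dh <- dhs[[t]] + dh_next
    dz <- dh * (cc$h_prev - cc$n) * cc$z * (1 - cc$z)
    dn <- dh * (1 - cc$z) * (1 - cc$n^2)
    dh_prev <- dh * cc$z
    g$Wn <- g$Wn + dn %*% t(cc$x)
    g$bn <- g$bn + rowSums(dn)
    dr_pre <- dn * cc$unh * cc$r * (1 - cc$r)
    g$Un <- g$Un + (dn * cc$r) %*% t(cc$h_prev)
    dh_prev <- dh_prev + t(p$Un) %*% (dn * cc$r)
    g$Wr <- g$Wr + dr_pre %*% t(cc$x)
    g$Ur <- g$Ur + dr_pre %*% t(cc$h_prev)
    g$br <- g$br + rowSums(dr_pre)
    dh_prev <- dh_prev + t(p$Ur) %*% dr_pre
    g$Wz <- g$Wz + dz %*% t(cc$x)
    g$Uz <- g$Uz + dz %*% t(cc$h_prev)
    g$bz <- g$bz + rowSums(dz)
    dh_prev <- dh_prev + t(p$Uz) %*% dz
    dX[[t]] <- t(p$Wz) %*% dz + t(p$Wr) %*% dr_pre + t(p$Wn) %*% dn
    dh_next <- dh_prev
  }
  list(dX = dX, grads = g)
}

# Bidirectional wrapper: concatenated [2U, B] outputs per step.
bigru_forward <- function(S, pf, pb) {
  T_ <- length(S)
  fw <- gru_forward(S, pf)
  bw <- gru_forward(rev(S), pb)
  out <- vector("list", T_)
  for (t in seq_len(T_))
    out[[t]] <- rbind(fw$hs[[t]], bw$hs[[T_ - t + 1L]])
  list(out = out, fw = fw, bw = bw)
}

bigru_backward <- function(dout, pf, pb, cache) {
  T_ <- length(dout)
  U <- nrow(pf$Wz)
  df <- lapply(dout, function(d) d[seq_len(U), , drop = FALSE])
  db <- lapply(seq_len(T_), function(t)
    dout[[T_ - t + 1L]][(U + 1L):(2L * U), , drop = FALSE])
  bf <- gru_backward(df, pf, cache$fw$cache)
  bb <- gru_backward(db, pb, cache$bw$cache)
  dX <- vector("list", T_)
  for (t in seq_len(T_))
    dX[[t]] <- bf$dX[[t]] + bb$dX[[T_ - t + 1L]]
  list(dX = dX, gf = bf$grads, gb = bb$grads)
}

# --- softmax cross-entropy --------------------------------------------------

softmax_cols <- function(Z) {
  Z <- Z - matrix(apply(Z, 2L, max), nrow(Z), ncol(Z), byrow = TRUE)
  E <- exp(Z)
  E / matrix(colSums(E), nrow(Z), ncol(Z), byrow = TRUE)
}

# labels: integer vector in 1..K; returns mean loss and dZ
xent_loss <- function(Z, labels) {
  P <- softmax_cols(Z)
  B <- ncol(Z)
  picked <- P[cbind(labels, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dZ <- P
  dZ[cbind(labels, seq_len(B))] <- dZ[cbind(labels, seq_len(B))] - 1
  list(loss = loss, dZ = dZ / B, probs = P)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  flat <- unlist_params(params)
  list(m = flat * 0, v = flat * 0, t = 0L)
}

unlist_params <- function(params) unlist(params, use.names = FALSE)

relist_params <- function(flat, skeleton) {
  utils::relist(flat, skeleton)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  p <- unlist_params(params)
  g <- unlist_params(grads)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  p <- p - lr * mhat / (sqrt(vhat) + eps)
  list(params = relist_params(p, params), state = state)
}
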