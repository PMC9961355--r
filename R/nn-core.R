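# Minimal dense/recurrent/convolutional network core.
#
# The forecasters are tiny (hundreds to a few thousand parameters), so the
# whole engine is vectorized base R: each architecture has an init, a
# batched forward that caches activations, and a hand-derived backward.
# Gradient correctness is pinned by finite-difference checks in the tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform init for a nin -> nout map
glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

glorot_vec <- function(nin, nout) as.vector(glorot(nin, nout))

add_rowvec <- function(M, b) sweep(M, 2L, b, `+`)

## ---- Adam ------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state,
                      lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- losses ----------------------------------------------------------

# value and gradient of the mean loss over a batch
loss_value <- function(pred, target, loss) {
  e <- pred - target
  if (loss == "MAE") mean(abs(e)) else mean(e * e)
}

loss_grad <- function(pred, target, loss) {
  e <- pred - target
  n <- length(e)
  if (loss == "MAE") sign(e) / n else 2 * e / n
}

## ---- vanilla RNN -----------------------------------------------------

rnn_init <- function(hidden) {
  H <- hidden
  list(Wx = glorot_vec(1, H), Wh = glorot(H, H), bh = numeric(H),
       Wo = glorot_vec(H, 1), bo = 0)
}

rnn_forward <- function(params, X, activation) {
  B <- nrow(X); Tn <- ncol(X); H <- length(params$bh)
  Hs <- vector("list", Tn)
  Hp <- matrix(0, B, H)
  for (t in seq_len(Tn)) {
    A <- outer(X[, t], params$Wx) + Hp %*% params$Wh
    Hs[[t]] <- tanh(add_rowvec(A, params$bh))
    Hp <- Hs[[t]]
  }
  pre <- as.vector(Hp %*% params$Wo) + params$bo
  out <- if (activation == "tanh") tanh(pre) else pre
  list(out = out, cache = list(X = X, Hs = Hs, pre = pre, out = out,
                               activation = activation))
}

rnn_backward <- function(params, cache, dout) {
  X <- cache$X; Hs <- cache$Hs
  B <- nrow(X); Tn <- ncol(X); H <- length(params$bh)
  dpre <- if (cache$activation == "tanh") dout * (1 - cache$out^2) else dout
  g <- list(Wx = numeric(H), Wh = matrix(0, H, H), bh = numeric(H),
            Wo = as.vector(t(Hs[[Tn]]) %*% dpre), bo = sum(dpre))
  dH <- outer(dpre, params$Wo)
  for (t in seq(Tn, 1L)) {
    dA <- dH * (1 - Hs[[t]]^2)
    Hprev <- if (t > 1L) Hs[[t - 1L]] else matrix(0, B, H)
    g$Wx <- g$Wx + as.vector(crossprod(X[, t], dA))
    g$Wh <- g$Wh + crossprod(Hprev, dA)
    g$bh <- g$bh + colSums(dA)
    dH <- dA %*% t(params$Wh)
  }
  g
}

## ---- GRU -------------------------------------------------------------

gru_init <- function(hidden) {
  H <- hidden
  list(Uz = glorot_vec(1, H), Wz = glorot(H, H), bz = numeric(H),
       Ur = glorot_vec(1, H), Wr = glorot(H, H), br = numeric(H),
       Uc = glorot_vec(1, H), Wc = glorot(H, H), bc = numeric(H),
       Wo = glorot_vec(H, 1), bo = 0)
}

gru_forward <- function(params, X, activation) {
  B <- nrow(X); Tn <- ncol(X); H <- length(params$bz)
  cache <- vector("list", Tn)
  Hp <- matrix(0, B, H)
  for (t in seq_len(Tn)) {
    x <- X[, t]
    z <- sigmoid(add_rowvec(outer(x, params$Uz) + Hp %*% params$Wz, params$bz))
    r <- sigmoid(add_rowvec(outer(x, params$Ur) + Hp %*% params$Wr, params$br))
    hr <- r * Hp
    cg <- tanh(add_rowvec(outer(x, params$Uc) + hr %*% params$Wc, params$bc))
    Hn <- (1 - z) * Hp + z * cg
    cache[[t]] <- list(x = x, Hp = Hp, z = z, r = r, hr = hr, cg = cg)
    Hp <- Hn
  }
  pre <- as.vector(Hp %*% params$Wo) + params$bo
  out <- if (activation == "tanh") tanh(pre) else pre
  list(out = out, cache = list(steps = cache, Hlast = Hp, pre = pre, out = out,
                               activation = activation))
}

gru_backward <- function(params, cache, dout) {
  steps <- cache$steps
  Tn <- length(steps); H <- length(params$bz)
  dpre <- if (cache$activation == "tanh") dout * (1 - cache$out^2) else dout
  g <- list(Uz = numeric(H), Wz = matrix(0, H, H), bz = numeric(H),
            Ur = numeric(H), Wr = matrix(0, H, H), br = numeric(H),
            Uc = numeric(H), Wc = matrix(0, H, H), bc = numeric(H),
            Wo = as.vector(t(cache$Hlast) %*% dpre), bo = sum(dpre))
  dH <- outer(dpre, params$Wo)
  for (t in seq(Tn, 1L)) {
    s <- steps[[t]]
    dz <- dH * (s$cg - s$Hp)
    dcg <- dH * s$z
    dHp <- dH * (1 - s$z)
    dac <- dcg * (1 - s$cg^2)
    g$Uc <- g$Uc + as.vector(crossprod(s$x, dac))
    g$Wc <- g$Wc + crossprod(s$hr, dac)
    g$bc <- g$bc + colSums(dac)
    dhr <- dac %*% t(params$Wc)
    dr <- dhr * s$Hp
    dHp <- dHp + dhr * s$r
    daz <- dz * s$z * (1 - s$z)
    g$Uz <- g$Uz + as.vector(crossprod(s$x, daz))
    g$Wz <- g$Wz + crossprod(s$Hp, daz)
    g$bz <- g$bz + colSums(daz)
    dHp <- dHp + daz %*% t(params$Wz)
    dar <- dr * s$r * (1 - s$r)
    g$Ur <- g$Ur + as.vector(crossprod(s$x, dar))
    g$Wr <- g$Wr + crossprod(s$Hp, dar)
    g$br <- g$br + colSums(dar)
    dHp <- dHp + dar %*% t(params$Wr)
    dH <- dHp
  }
  g
}

## ---- LSTM ------------------------------------------------------------

lstm_init <- function(hidden) {
  H <- hidden
  list(Ui = glorot_vec(1, H), Wi = glorot(H, H), bi = numeric(H),
       Uf = glorot_vec(1, H), Wf = glorot(H, H), bf = rep(1, H),  # forget bias 1
       Uo = glorot_vec(1, H), Wog = glorot(H, H), bog = numeric(H),
       Ug = glorot_vec(1, H), Wg = glorot(H, H), bg = numeric(H),
       Wo = glorot_vec(H, 1), bo = 0)
}

lstm_forward <- function(params, X, activation) {
  B <- nrow(X); Tn <- ncol(X); H <- length(params$bi)
  cache <- vector("list", Tn)
  Hp <- matrix(0, B, H); Cp <- matrix(0, B, H)
  for (t in seq_len(Tn)) {
    x <- X[, t]
    i <- sigmoid(add_rowvec(outer(x, params$Ui) + Hp %*% params$Wi, params$bi))
    f <- sigmoid(add_rowvec(outer(x, params$Uf) + Hp %*% params$Wf, params$bf))
    o <- sigmoid(add_rowvec(outer(x, params$Uo) + Hp %*% params$Wog, params$bog))
    gg <- tanh(add_rowvec(outer(x, params$Ug) + Hp %*% params$Wg, params$bg))
    Cn <- f * Cp + i * gg
    tC <- tanh(Cn)
    Hn <- o * tC
    cache[[t]] <- list(x = x, Hp = Hp, Cp = Cp, i = i, f = f, o = o, g = gg,
                       tC = tC)
    Hp <- Hn; Cp <- Cn
  }
  pre <- as.vector(Hp %*% params$Wo) + params$bo
  out <- if (activation == "tanh") tanh(pre) else pre
  list(out = out, cache = list(steps = cache, Hlast = Hp, pre = pre, out = out,
                               activation = activation))
}

lstm_backward <- function(params, cache, dout) {
  steps <- cache$steps
  Tn <- length(steps); H <- length(params$bi)
  B <- length(dout)
  dpre <- if (cache$activation == "tanh") dout * (1 - cache$out^2) else dout
  g <- list(Ui = numeric(H), Wi = matrix(0, H, H), bi = numeric(H),
            Uf = numeric(H), Wf = matrix(0, H, H), bf = numeric(H),
            Uo = numeric(H), Wog = matrix(0, H, H), bog = numeric(H),
            Ug = numeric(H), Wg = matrix(0, H, H), bg = numeric(H),
            Wo = as.vector(t(cache$Hlast) %*% dpre), bo = sum(dpre))
  dH <- outer(dpre, params$Wo)
  dC <- matrix(0, B, H)
  for (t in seq(Tn, 1L)) {
    s <- steps[[t]]
    do_ <- dH * s$tC
    dC <- dC + dH * s$o * (1 - s$tC^2)
    di <- dC * s$g
    dg <- dC * s$i
    df <- dC * s$Cp
    dCp <- dC * s$f
    dai <- di * s$i * (1 - s$i)
    daf <- df * s$f * (1 - s$f)
    dao <- do_ * s$o * (1 - s$o)
    dag <- dg * (1 - s$g^2)
    g$Ui <- g$Ui + as.vector(crossprod(s$x, dai))
    g$Wi <- g$Wi + crossprod(s$Hp, dai)
    g$bi <- g$bi + colSums(dai)
    g$Uf <- g$Uf + as.vector(crossprod(s$x, daf))
    g$Wf <- g$Wf + crossprod(s$Hp, daf)
    g$bf <- g$bf + colSums(daf)
    g$Uo <- g$Uo + as.vector(crossprod(s$x, dao))
    g$Wog <- g$Wog + crossprod(s$Hp, dao)
    g$bog <- g$bog + colSums(dao)
    g$Ug <- g$Ug + as.vector(crossprod(s$x, dag))
    g$Wg <- g$Wg + crossprod(s$Hp, dag)
    g$bg <- g$bg + colSums(dag)
    dH <- dai %*% t(params$Wi) + daf %*% t(params$Wf) +
      dao %*% t(params$Wog) + dag %*% t(params$Wg)
    dC <- dCp
  }
  g
}

## ---- encoder CNN -----------------------------------------------------
#
# 4x4x1 input -> conv 2x2 (4 ch, tanh) -> 3x3x4 -> conv 2x2 (8 ch, tanh)
# -> 2x2x8 -> conv 2x2 (16 ch, tanh) -> 1x1x16 -> dense 16 -> 1 (tanh).
# Feature maps are stored batch-major as B x (positions * channels)
# matrices, channel-blocked: column (c-1)*Q + q for channel c, row-major
# spatial position q.  Kernels are K x Cout matrices whose rows follow the
# patch ordering produced by conv_patch_idx().

conv_patch_idx <- function(hin, win, cin) {
  hout <- hin - 1L; wout <- win - 1L
  P <- hin * win
  Q <- hout * wout
  idx <- matrix(0L, Q, 4L * cin)
  q <- 0L
  for (ro in seq_len(hout)) for (co in seq_len(wout)) {
    q <- q + 1L
    k <- 0L
    for (ch in seq_len(cin)) for (dr in 0:1) for (dc in 0:1) {
      k <- k + 1L
      idx[q, k] <- (ch - 1L) * P + (ro + dr - 1L) * win + (co + dc)
    }
  }
  idx
}

CNN_GEOM <- list(
  list(hin = 4L, win = 4L, cin = 1L, cout = 4L),
  list(hin = 3L, win = 3L, cin = 4L, cout = 8L),
  list(hin = 2L, win = 2L, cin = 8L, cout = 16L)
)
CNN_IDX <- lapply(CNN_GEOM, function(g) conv_patch_idx(g$hin, g$win, g$cin))

cnn_init <- function(hidden = NULL) {
  ps <- list()
  for (l in seq_along(CNN_GEOM)) {
    g <- CNN_GEOM[[l]]
    ps[[paste0("W", l)]] <- glorot(4L * g$cin, g$cout)
    ps[[paste0("b", l)]] <- numeric(g$cout)
  }
  ps$Wo <- glorot_vec(16, 1)
  ps$bo <- 0
  ps
}

conv_layer_forward <- function(Xmat, W, b, idx, Q, cout) {
  B <- nrow(Xmat)
  out <- matrix(0, B, Q * cout)
  for (q in seq_len(Q)) {
    pre <- add_rowvec(Xmat[, idx[q, ], drop = FALSE] %*% W, b)
    out[, (seq_len(cout) - 1L) * Q + q] <- tanh(pre)
  }
  out
}

cnn_forward <- function(params, X, activation) {
  maps <- vector("list", 4L)
  maps[[1L]] <- X  # B x 16, row-major 4x4, one channel
  for (l in 1:3) {
    g <- CNN_GEOM[[l]]
    Q <- (g$hin - 1L) * (g$win - 1L)
    maps[[l + 1L]] <- conv_layer_forward(maps[[l]],
                                         params[[paste0("W", l)]],
                                         params[[paste0("b", l)]],
                                         CNN_IDX[[l]], Q, g$cout)
  }
  pre <- as.vector(maps[[4L]] %*% params$Wo) + params$bo
  out <- if (activation == "tanh") tanh(pre) else pre
  list(out = out, cache = list(maps = maps, pre = pre, out = out,
                               activation = activation))
}

cnn_backward <- function(params, cache, dout) {
  maps <- cache$maps
  B <- length(dout)
  dpre <- if (cache$activation == "tanh") dout * (1 - cache$out^2) else dout
  g <- list()
  g$Wo <- as.vector(t(maps[[4L]]) %*% dpre)
  g$bo <- sum(dpre)
  dmap <- outer(dpre, params$Wo)  # gradient wrt layer-3 output (B x 16)
  for (l in 3:1) {
    geo <- CNN_GEOM[[l]]
    Q <- (geo$hin - 1L) * (geo$win - 1L)
    cout <- geo$cout
    idx <- CNN_IDX[[l]]
    W <- params[[paste0("W", l)]]
    out <- maps[[l + 1L]]
    Xin <- maps[[l]]
    gW <- W * 0; gb <- numeric(cout)
    dX <- Xin * 0
    for (q in seq_len(Q)) {
      cols <- (seq_len(cout) - 1L) * Q + q
      dpre_q <- dmap[, cols, drop = FALSE] * (1 - out[, cols, drop = FALSE]^2)
      Xp <- Xin[, idx[q, ], drop = FALSE]
      gW <- gW + crossprod(Xp, dpre_q)
      gb <- gb + colSums(dpre_q)
      dX[, idx[q, ]] <- dX[, idx[q, ], drop = FALSE] + dpre_q %*% t(W)
    }
    g[[paste0("W", l)]] <- gW
    g[[paste0("b", l)]] <- gb
    dmap <- dX
  }
  g
}

## ---- dispatch --------------------------------------------------------

nn_engine <- function(family) {
  switch(family,
         rnn = list(init = rnn_init, forward = rnn_forward, backward = rnn_backward),
         gru = list(init = gru_init, forward = gru_forward, backward = gru_backward),
         lstm = list(init = lstm_init, forward = lstm_forward, backward = lstm_backward),
         cnn = list(init = cnn_init, forward = cnn_forward, backward = cnn_backward),
         stop("unknown engine family: ", family, call. = FALSE))
}

nn_param_count <- function(params) {
  sum(vapply(params, length, integer(1)))
}
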