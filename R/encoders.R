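# Caption-encoder bridges: forward passes and analytic gradients.
#
# All encoders consume sequences of grounded word vectors (dimension c) and
# emit a predicted image vector (dimension D_img). Batched captions are
# handled as lists of integer index vectors into a shared grounded matrix
# Gv; padding is realized by masking, never by special tokens.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform initialization; draws come from the current RNG stream so
# the whole model is reproducible from one seed.
.glorot <- function(fan_in, fan_out, nrow = fan_in, ncol = fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# Accumulate rows into a matrix by index (duplicates sum).
.index_add <- function(target, idx, rows) {
  rs <- rowsum(rows, group = idx, reorder = FALSE)
  at <- as.integer(rownames(rs))
  target[at, ] <- target[at, , drop = FALSE] + rs
  target
}

# -- parameter initialization ----------------------------------------------

.init_params <- function(config) {
  d <- config$d; c <- config$c; D <- config$D_img
  U <- config$encoder_units; kind <- config$encoder_kind
  params <- list(M = .glorot(d, c))
  if (config$activation_layers > 1L)
    for (l in 2:config$activation_layers)
      params[[paste0("M", l)]] <- .glorot(c, c)
  if (kind == "bow") {
    params$W1 <- .glorot(c, U); params$b1 <- numeric(U)
    params$W2 <- .glorot(U, D); params$b2 <- numeric(D)
  } else if (kind %in% c("lstm", "gru")) {
    gmult <- if (kind == "lstm") 4L else 3L
    for (l in seq_len(config$encoder_layers)) {
      inp <- if (l == 1L) c else U
      params[[paste0("Wx", l)]] <- .glorot(inp, U, inp, gmult * U)
      params[[paste0("Wh", l)]] <- .glorot(U, U, U, gmult * U)
      params[[paste0("b", l)]] <- numeric(gmult * U)
      if (config$init_state == "learned") {
        params[[paste0("h0_", l)]] <- matrix(stats::runif(U, -0.05, 0.05), 1L)
        if (kind == "lstm")
          params[[paste0("c0_", l)]] <-
            matrix(stats::runif(U, -0.05, 0.05), 1L)
      }
    }
    if (U != D) {
      params$Wp <- .glorot(U, D); params$bp <- numeric(D)
    }
  } else if (kind == "transformer") {
    m <- U; ff <- 2L * m
    params$We <- .glorot(c, m)
    for (l in seq_len(config$encoder_layers)) {
      p <- paste0("t", l, "_")
      params[[paste0(p, "Wq")]] <- .glorot(m, m)
      params[[paste0(p, "Wk")]] <- .glorot(m, m)
      params[[paste0(p, "Wv")]] <- .glorot(m, m)
      params[[paste0(p, "Wo")]] <- .glorot(m, m)
      params[[paste0(p, "g1")]] <- rep(1, m)
      params[[paste0(p, "be1")]] <- numeric(m)
      params[[paste0(p, "W1")]] <- .glorot(m, ff)
      params[[paste0(p, "b1")]] <- numeric(ff)
      params[[paste0(p, "W2")]] <- .glorot(ff, m)
      params[[paste0(p, "b2")]] <- numeric(m)
      params[[paste0(p, "g2")]] <- rep(1, m)
      params[[paste0(p, "be2")]] <- numeric(m)
    }
    params$Wp <- .glorot(m, D); params$bp <- numeric(D)
  }
  # word_level: alignment stack only
  params
}

# -- BoW bridge -------------------------------------------------------------

.bow_forward <- function(params, cap_idx, Gv) {
  lens <- lengths(cap_idx)
  X <- t(vapply(cap_idx, function(ii)
    colMeans(Gv[ii, , drop = FALSE]), numeric(ncol(Gv))))
  H1 <- tanh(sweep(X %*% params$W1, 2L, params$b1, `+`))
  pred <- sweep(H1 %*% params$W2, 2L, params$b2, `+`)
  list(pred = pred, cache = list(X = X, H1 = H1, cap_idx = cap_idx,
                                 lens = lens))
}

.bow_backward <- function(params, cache, dpred, nV) {
  H1 <- cache$H1; X <- cache$X
  grads <- list(
    W2 = crossprod(H1, dpred), b2 = colSums(dpred))
  dH1 <- dpred %*% t(params$W2)
  dZ1 <- dH1 * (1 - H1^2)
  grads$W1 <- crossprod(X, dZ1)
  grads$b1 <- colSums(dZ1)
  dX <- dZ1 %*% t(params$W1)
  dGv <- matrix(0, nV, ncol(dX))
  for (b in seq_along(cache$cap_idx)) {
    ii <- cache$cap_idx[[b]]
    dGv <- .index_add(dGv, ii,
                      matrix(dX[b, ] / cache$lens[b], length(ii),
                             ncol(dX), byrow = TRUE))
  }
  list(grads = grads, dGv = dGv)
}

# -- recurrent bridges (shared layer machinery) -----------------------------

# Build padded per-timestep index matrix and mask from a list of captions.
.pad_batch <- function(cap_idx) {
  lens <- lengths(cap_idx)
  Tm <- max(lens)
  B <- length(cap_idx)
  idx <- matrix(1L, B, Tm)
  mask <- matrix(0, B, Tm)
  for (b in seq_len(B)) {
    idx[b, seq_len(lens[b])] <- cap_idx[[b]]
    mask[b, seq_len(lens[b])] <- 1
  }
  list(idx = idx, mask = mask, lens = lens, Tm = Tm, B = B)
}

.lstm_layer_forward <- function(Wx, Wh, b, X_seq, mask, h0, c0) {
  B <- nrow(X_seq[[1L]]); H <- ncol(Wh) / 4L; Tm <- length(X_seq)
  Hprev <- matrix(rep(h0, each = B), B)
  Cprev <- matrix(rep(c0, each = B), B)
  steps <- vector("list", Tm); H_seq <- vector("list", Tm)
  iH <- seq_len(H)
  for (t in seq_len(Tm)) {
    A <- sweep(X_seq[[t]] %*% Wx + Hprev %*% Wh, 2L, b, `+`)
    i <- .sigmoid(A[, iH, drop = FALSE])
    f <- .sigmoid(A[, H + iH, drop = FALSE])
    g <- tanh(A[, 2L * H + iH, drop = FALSE])
    o <- .sigmoid(A[, 3L * H + iH, drop = FALSE])
    c_new <- f * Cprev + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    m <- mask[, t]
    Cm <- m * c_new + (1 - m) * Cprev
    Hm <- m * h_new + (1 - m) * Hprev
    steps[[t]] <- list(i = i, f = f, g = g, o = o, c_new = c_new, tc = tc,
                       Cprev = Cprev, Hprev = Hprev, m = m)
    Hprev <- Hm; Cprev <- Cm
    H_seq[[t]] <- Hm
  }
  list(H_seq = H_seq, steps = steps, h_final = Hprev)
}

.lstm_layer_backward <- function(Wx, Wh, X_seq, cache, dH_seq, learned_init) {
  Tm <- length(X_seq); H <- ncol(Wh) / 4L
  B <- nrow(X_seq[[1L]])
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dH <- matrix(0, B, H); dC <- matrix(0, B, H)
  dX_seq <- vector("list", Tm)
  for (t in rev(seq_len(Tm))) {
    st <- cache$steps[[t]]
    dH <- dH + dH_seq[[t]]
    m <- st$m
    dh_new <- m * dH
    dc_new <- m * dC + dh_new * st$o * (1 - st$tc^2)
    do <- dh_new * st$tc
    di <- dc_new * st$g
    dg <- dc_new * st$i
    df <- dc_new * st$Cprev
    dA <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    dWx <- dWx + crossprod(X_seq[[t]], dA)
    dWh <- dWh + crossprod(st$Hprev, dA)
    db <- db + colSums(dA)
    dX_seq[[t]] <- dA %*% t(Wx)
    dH <- (1 - m) * dH + dA %*% t(Wh)
    dC <- (1 - m) * dC + dc_new * st$f
  }
  out <- list(dWx = dWx, dWh = dWh, db = db, dX_seq = dX_seq)
  if (learned_init) {
    out$dh0 <- matrix(colSums(dH), 1L)
    out$dc0 <- matrix(colSums(dC), 1L)
  }
  out
}

.gru_layer_forward <- function(Wx, Wh, b, X_seq, mask, h0) {
  B <- nrow(X_seq[[1L]]); H <- ncol(Wh) / 3L; Tm <- length(X_seq)
  Hprev <- matrix(rep(h0, each = B), B)
  steps <- vector("list", Tm); H_seq <- vector("list", Tm)
  iH <- seq_len(H)
  for (t in seq_len(Tm)) {
    A <- sweep(X_seq[[t]] %*% Wx, 2L, b, `+`)
    Bh <- Hprev %*% Wh
    r <- .sigmoid(A[, iH, drop = FALSE] + Bh[, iH, drop = FALSE])
    z <- .sigmoid(A[, H + iH, drop = FALSE] + Bh[, H + iH, drop = FALSE])
    Bn <- Bh[, 2L * H + iH, drop = FALSE]
    n <- tanh(A[, 2L * H + iH, drop = FALSE] + r * Bn)
    h_new <- (1 - z) * n + z * Hprev
    m <- mask[, t]
    Hm <- m * h_new + (1 - m) * Hprev
    steps[[t]] <- list(r = r, z = z, n = n, Bn = Bn, Hprev = Hprev, m = m)
    Hprev <- Hm
    H_seq[[t]] <- Hm
  }
  list(H_seq = H_seq, steps = steps, h_final = Hprev)
}

.gru_layer_backward <- function(Wx, Wh, X_seq, cache, dH_seq, learned_init) {
  Tm <- length(X_seq); H <- ncol(Wh) / 3L
  B <- nrow(X_seq[[1L]])
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, H, 3L * H)
  db <- numeric(3L * H)
  dH <- matrix(0, B, H)
  dX_seq <- vector("list", Tm)
  for (t in rev(seq_len(Tm))) {
    st <- cache$steps[[t]]
    dH <- dH + dH_seq[[t]]
    m <- st$m
    dh_new <- m * dH
    dHprev <- (1 - m) * dH + dh_new * st$z
    dz <- dh_new * (st$Hprev - st$n)
    dn <- dh_new * (1 - st$z)
    dan <- dn * (1 - st$n^2)
    dr <- dan * st$Bn
    dBn <- dan * st$r
    dz_pre <- dz * st$z * (1 - st$z)
    dr_pre <- dr * st$r * (1 - st$r)
    dA <- cbind(dr_pre, dz_pre, dan)
    dBh <- cbind(dr_pre, dz_pre, dBn)
    dWx <- dWx + crossprod(X_seq[[t]], dA)
    dWh <- dWh + crossprod(st$Hprev, dBh)
    db <- db + colSums(dA)
    dX_seq[[t]] <- dA %*% t(Wx)
    dH <- dHprev + dBh %*% t(Wh)
  }
  out <- list(dWx = dWx, dWh = dWh, db = db, dX_seq = dX_seq)
  if (learned_init) out$dh0 <- matrix(colSums(dH), 1L)
  out
}

.rnn_forward <- function(params, config, cap_idx, Gv) {
  pad <- .pad_batch(cap_idx)
  kind <- config$encoder_kind
  U <- config$encoder_units
  X_seq <- lapply(seq_len(pad$Tm), function(t)
    Gv[pad$idx[, t], , drop = FALSE])
  layer_in <- X_seq
  layers <- vector("list", config$encoder_layers)
  for (l in seq_len(config$encoder_layers)) {
    h0 <- if (config$init_state == "learned")
      params[[paste0("h0_", l)]] else numeric(U)
    if (kind == "lstm") {
      c0 <- if (config$init_state == "learned")
        params[[paste0("c0_", l)]] else numeric(U)
      lay <- .lstm_layer_forward(params[[paste0("Wx", l)]],
                                 params[[paste0("Wh", l)]],
                                 params[[paste0("b", l)]],
                                 layer_in, pad$mask, h0, c0)
    } else {
      lay <- .gru_layer_forward(params[[paste0("Wx", l)]],
                                params[[paste0("Wh", l)]],
                                params[[paste0("b", l)]],
                                layer_in, pad$mask, h0)
    }
    layers[[l]] <- list(cache = lay, X_seq = layer_in)
    layer_in <- lay$H_seq
  }
  h_final <- layers[[config$encoder_layers]]$cache$h_final
  if (!is.null(params$Wp))
    pred <- sweep(h_final %*% params$Wp, 2L, params$bp, `+`)
  else pred <- h_final
  list(pred = pred,
       cache = list(pad = pad, layers = layers, h_final = h_final))
}

.rnn_backward <- function(params, config, cache, dpred, nV) {
  pad <- cache$pad
  kind <- config$encoder_kind
  grads <- list()
  if (!is.null(params$Wp)) {
    grads$Wp <- crossprod(cache$h_final, dpred)
    grads$bp <- colSums(dpred)
    dh_final <- dpred %*% t(params$Wp)
  } else dh_final <- dpred
  zero <- matrix(0, pad$B, config$encoder_units)
  dH_seq <- rep(list(zero), pad$Tm)
  dH_seq[[pad$Tm]] <- dh_final
  learned <- config$init_state == "learned"
  for (l in rev(seq_len(config$encoder_layers))) {
    lay <- cache$layers[[l]]
    if (kind == "lstm") {
      bk <- .lstm_layer_backward(params[[paste0("Wx", l)]],
                                 params[[paste0("Wh", l)]],
                                 lay$X_seq, lay$cache, dH_seq, learned)
      if (learned) grads[[paste0("c0_", l)]] <- bk$dc0
    } else {
      bk <- .gru_layer_backward(params[[paste0("Wx", l)]],
                                params[[paste0("Wh", l)]],
                                lay$X_seq, lay$cache, dH_seq, learned)
    }
    grads[[paste0("Wx", l)]] <- bk$dWx
    grads[[paste0("Wh", l)]] <- bk$dWh
    grads[[paste0("b", l)]] <- bk$db
    if (learned) grads[[paste0("h0_", l)]] <- bk$dh0
    dH_seq <- bk$dX_seq
  }
  # dH_seq now holds gradients w.r.t. the grounded input vectors
  dGv <- matrix(0, nV, config$c)
  for (t in seq_len(pad$Tm)) {
    live <- pad$mask[, t] == 1
    if (!any(live)) next
    dGv <- .index_add(dGv, pad$idx[live, t],
                      dH_seq[[t]][live, , drop = FALSE])
  }
  list(grads = grads, dGv = dGv)
}

# -- transformer-encoder bridge (processed per sample) ----------------------

.sinusoidal_pe <- function(n, m) {
  pos <- seq_len(n) - 1L
  pe <- matrix(0, n, m)
  for (j in seq_len(m)) {
    i2 <- (j - 1L) %/% 2L
    ang <- pos / 10000^(2 * i2 / m)
    pe[, j] <- if (j %% 2L == 1L) sin(ang) else cos(ang)
  }
  pe
}

.layernorm_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  Xhat <- Xc * inv
  Y <- sweep(Xhat * matrix(gamma, nrow(X), ncol(X), byrow = TRUE), 2L,
             beta, `+`)
  list(Y = Y, Xhat = Xhat, inv = inv)
}

.layernorm_backward <- function(cache, gamma, dY) {
  Xhat <- cache$Xhat; inv <- cache$inv
  dXhat <- dY * matrix(gamma, nrow(dY), ncol(dY), byrow = TRUE)
  m1 <- rowMeans(dXhat)
  m2 <- rowMeans(dXhat * Xhat)
  dX <- inv * (dXhat - m1 - Xhat * m2)
  list(dX = dX, dgamma = colSums(dY * Xhat), dbeta = colSums(dY))
}

.tf_sample_forward <- function(params, config, G) {
  m <- config$encoder_units; nh <- config$n_heads; dk <- m %/% nh
  n <- nrow(G)
  X <- G %*% params$We + .sinusoidal_pe(n, m)
  X0 <- X
  layers <- vector("list", config$encoder_layers)
  for (l in seq_len(config$encoder_layers)) {
    p <- paste0("t", l, "_")
    Q <- X %*% params[[paste0(p, "Wq")]]
    K <- X %*% params[[paste0(p, "Wk")]]
    V <- X %*% params[[paste0(p, "Wv")]]
    Hcat <- matrix(0, n, m)
    heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
      S <- S - apply(S, 1L, max)
      P <- exp(S); P <- P / rowSums(P)
      Hcat[, cols] <- P %*% V[, cols, drop = FALSE]
      heads[[h]] <- P
    }
    O <- Hcat %*% params[[paste0(p, "Wo")]]
    ln1 <- .layernorm_forward(X + O, params[[paste0(p, "g1")]],
                              params[[paste0(p, "be1")]])
    Z1 <- sweep(ln1$Y %*% params[[paste0(p, "W1")]], 2L,
                params[[paste0(p, "b1")]], `+`)
    A1 <- pmax(Z1, 0)
    F2 <- sweep(A1 %*% params[[paste0(p, "W2")]], 2L,
                params[[paste0(p, "b2")]], `+`)
    ln2 <- .layernorm_forward(ln1$Y + F2, params[[paste0(p, "g2")]],
                              params[[paste0(p, "be2")]])
    layers[[l]] <- list(Xin = X, Q = Q, K = K, V = V, Hcat = Hcat,
                        heads = heads, ln1 = ln1, Z1 = Z1, A1 = A1,
                        ln2 = ln2)
    X <- ln2$Y
  }
  pool <- colMeans(X)
  pred <- drop(pool %*% params$Wp) + params$bp
  list(pred = pred, cache = list(G = G, X0 = X0, layers = layers,
                                 Xout = X, pool = pool, n = n))
}

.tf_sample_backward <- function(params, config, cache, dpred) {
  m <- config$encoder_units; nh <- config$n_heads; dk <- m %/% nh
  n <- cache$n
  grads <- list(Wp = cache$pool %o% dpred, bp = dpred)
  dpool <- drop(params$Wp %*% dpred)
  dX <- matrix(dpool / n, n, m, byrow = TRUE)
  for (l in rev(seq_len(config$encoder_layers))) {
    p <- paste0("t", l, "_")
    lc <- cache$layers[[l]]
    b2k <- .layernorm_backward(lc$ln2, params[[paste0(p, "g2")]], dX)
    grads[[paste0(p, "g2")]] <- b2k$dgamma
    grads[[paste0(p, "be2")]] <- b2k$dbeta
    dRes2 <- b2k$dX                       # w.r.t. ln1$Y + F2
    dF2 <- dRes2
    grads[[paste0(p, "W2")]] <- crossprod(lc$A1, dF2)
    grads[[paste0(p, "b2")]] <- colSums(dF2)
    dA1 <- dF2 %*% t(params[[paste0(p, "W2")]])
    dZ1 <- dA1 * (lc$Z1 > 0)
    grads[[paste0(p, "W1")]] <- crossprod(lc$ln1$Y, dZ1)
    grads[[paste0(p, "b1")]] <- colSums(dZ1)
    dY1 <- dRes2 + dZ1 %*% t(params[[paste0(p, "W1")]])
    b1k <- .layernorm_backward(lc$ln1, params[[paste0(p, "g1")]], dY1)
    grads[[paste0(p, "g1")]] <- b1k$dgamma
    grads[[paste0(p, "be1")]] <- b1k$dbeta
    dRes1 <- b1k$dX                       # w.r.t. Xin + O
    dO <- dRes1
    grads[[paste0(p, "Wo")]] <- crossprod(lc$Hcat, dO)
    dHcat <- dO %*% t(params[[paste0(p, "Wo")]])
    dQ <- matrix(0, n, m); dK <- matrix(0, n, m); dV <- matrix(0, n, m)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      P <- lc$heads[[h]]
      dH_h <- dHcat[, cols, drop = FALSE]
      dV[, cols] <- crossprod(P, dH_h)
      dP <- dH_h %*% t(lc$V[, cols, drop = FALSE])
      dS <- P * (dP - rowSums(dP * P))
      dQ[, cols] <- dS %*% lc$K[, cols, drop = FALSE] / sqrt(dk)
      dK[, cols] <- crossprod(dS, lc$Q[, cols, drop = FALSE]) / sqrt(dk)
    }
    acc <- function(nm, val) {
      cur <- grads[[nm]]
      grads[[nm]] <<- if (is.null(cur)) val else cur + val
    }
    acc(paste0(p, "Wq"), crossprod(lc$Xin, dQ))
    acc(paste0(p, "Wk"), crossprod(lc$Xin, dK))
    acc(paste0(p, "Wv"), crossprod(lc$Xin, dV))
    dX <- dRes1 + dQ %*% t(params[[paste0(p, "Wq")]]) +
      dK %*% t(params[[paste0(p, "Wk")]]) +
      dV %*% t(params[[paste0(p, "Wv")]])
  }
  grads$We <- crossprod(cache$G, dX)
  dG <- dX %*% t(params$We)
  list(grads = grads, dG = dG)
}

.tf_forward <- function(params, config, cap_idx, Gv) {
  caches <- vector("list", length(cap_idx))
  pred <- matrix(0, length(cap_idx), config$D_img)
  for (b in seq_along(cap_idx)) {
    fw <- .tf_sample_forward(params, config,
                             Gv[cap_idx[[b]], , drop = FALSE])
    pred[b, ] <- fw$pred
    caches[[b]] <- fw$cache
  }
  list(pred = pred, cache = list(caches = caches, cap_idx = cap_idx))
}

.tf_backward <- function(params, config, cache, dpred, nV) {
  grads <- NULL
  dGv <- matrix(0, nV, config$c)
  for (b in seq_along(cache$cap_idx)) {
    bk <- .tf_sample_backward(params, config, cache$caches[[b]], dpred[b, ])
    grads <- if (is.null(grads)) bk$grads
             else mapply(`+`, grads, bk$grads[names(grads)],
                         SIMPLIFY = FALSE)
    dGv <- .index_add(dGv, cache$cap_idx[[b]], bk$dG)
  }
  list(grads = grads, dGv = dGv)
}

# -- shared dispatch --------------------------------------------------------

.encoder_forward <- function(params, config, cap_idx, Gv) {
  switch(config$encoder_kind,
         bow = .bow_forward(params, cap_idx, Gv),
         lstm = ,
         gru = .rnn_forward(params, config, cap_idx, Gv),
         transformer = .tf_forward(params, config, cap_idx, Gv),
         stop("no encoder forward for kind ", config$encoder_kind))
}

.encoder_backward <- function(params, config, cache, dpred, nV) {
  switch(config$encoder_kind,
         bow = .bow_backward(params, cache, dpred, nV),
         lstm = ,
         gru = .rnn_backward(params, config, cache, dpred, nV),
         transformer = .tf_backward(params, config, cache, dpred, nV),
         stop("no encoder backward for kind ", config$encoder_kind))
}

#' Encode a caption's grounded vectors as an image-vector prediction
#'
#' Runs the model's bridge over a nonempty sequence of grounded word
#' vectors: LSTM/GRU return the final-step hidden state (through the
#' projection head when the hidden size differs from the image dimension);
#' BoW averages the sequence, applies a tanh hidden layer and a linear
#' output; the transformer variant stacks self-attention encoder layers
#' (sinusoidal position encoding, mean pooling) followed by a linear output.
#' The word-level bridge has no sequence encoder (see [train_grounding()]).
#'
#' @param model a `GroundingModel`.
#' @param G n x c matrix of grounded vectors, n >= 1.
#' @return numeric vector of length `D_img`.
#' @export
encode_caption <- function(model, G) {
  stopifnot(inherits(model, "GroundingModel"))
  if (model$config$encoder_kind == "word_level")
    stop("encode_caption: the word-level bridge has no sequence encoder")
  G <- as.matrix(G)
  if (nrow(G) == 0) stop("encode_caption: empty caption")
  if (ncol(G) != model$config$c)
    stop("encode_caption: grounded dimension ", ncol(G),
         " != model c ", model$config$c)
  fw <- .encoder_forward(model$params, model$config, list(seq_len(nrow(G))),
                         G)
  drop(fw$pred)
}
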