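# Vectorized (Bi-)LSTM + FFN regression network with hand-derived
# backpropagation through time. Layout conventions:
#   * sequences: list over time steps t = 1..T of B x I matrices
#   * gates packed column-wise as [i | f | g | o], each H wide
#   * right padding; padded rows carry zero input and receive zero gradient
#     because pooling masks them, so cells can be computed uniformly.
# Gradients are verified against central finite differences in the tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

addb <- function(M, b) M + rep(b, each = nrow(M))

# Per-sample reversal of the valid prefix of a padded sequence; an
# involution on valid positions, zero at padding. Used to run the backward
# direction of a Bi-LSTM with ordinary forward cells, and reused to route
# gradients (the map is a permutation, so it is its own transpose).
reverse_seq <- function(X, lens) {
  T_max <- length(X)
  out <- lapply(X, function(m) matrix(0, nrow(m), ncol(m)))
  for (b in seq_along(lens)) {
    lb <- lens[b]
    for (t in seq_len(lb)) out[[t]][b, ] <- X[[lb - t + 1L]][b, ]
  }
  out
}

lstm_cell_forward <- function(X, W, U, b, H) {
  T_max <- length(X)
  B <- nrow(X[[1L]])
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  Hs <- vector("list", T_max)
  cache <- vector("list", T_max)
  idx <- list(i = 1:H, f = (H + 1):(2 * H), g = (2 * H + 1):(3 * H),
              o = (3 * H + 1):(4 * H))
  for (t in seq_len(T_max)) {
    z <- addb(X[[t]] %*% W + h %*% U, b)
    gi <- sigmoid(z[, idx$i, drop = FALSE])
    gf <- sigmoid(z[, idx$f, drop = FALSE])
    gg <- tanh(z[, idx$g, drop = FALSE])
    go <- sigmoid(z[, idx$o, drop = FALSE])
    c_new <- gf * cc + gi * gg
    tc <- tanh(c_new)
    cache[[t]] <- list(x = X[[t]], h_prev = h, c_prev = cc,
                       i = gi, f = gf, g = gg, o = go, tc = tc)
    cc <- c_new
    h <- go * tc
    Hs[[t]] <- h
  }
  list(H = Hs, cache = cache)
}

lstm_cell_backward <- function(dH, cache, W, U) {
  T_max <- length(dH)
  B <- nrow(dH[[1L]])
  H <- ncol(dH[[1L]])
  dW <- matrix(0, nrow(W), ncol(W))
  dU <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dX <- vector("list", T_max)
  dh_carry <- matrix(0, B, H)
  dc_carry <- matrix(0, B, H)
  for (t in rev(seq_len(T_max))) {
    cc <- cache[[t]]
    dh <- dH[[t]] + dh_carry
    dc <- dc_carry + dh * cc$o * (1 - cc$tc^2)
    do_ <- dh * cc$tc
    df <- dc * cc$c_prev
    di <- dc * cc$g
    dg <- dc * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cc$x, dz)
    dU <- dU + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dX[[t]] <- dz %*% t(W)
    dh_carry <- dz %*% t(U)
    dc_carry <- dc * cc$f
  }
  list(dX = dX, dW = dW, dU = dU, db = db)
}

runif_mat <- function(nr, nc, k) matrix(stats::runif(nr * nc, -k, k), nr, nc)

# Parameter initialization; uniform(-1/sqrt(H), 1/sqrt(H)) for recurrent
# weights (with +1 forget-gate bias), fan-in scaled elsewhere.
nn_init <- function(config, fixed_in = 8L, step_in = 4L) {
  H <- config$hidden_size
  Fh <- config$ffn_hidden
  dirs <- if (config$bidirectional) 2L else 1L
  with_seed(config$seed, {
    k <- 1 / sqrt(H)
    lstm <- lapply(seq_len(config$num_layers), function(l) {
      I <- if (l == 1L) step_in else H * dirs
      lapply(seq_len(dirs), function(d) {
        b <- stats::runif(4 * H, -k, k)
        b[(H + 1):(2 * H)] <- b[(H + 1):(2 * H)] + 1
        list(W = runif_mat(I, 4 * H, k), U = runif_mat(H, 4 * H, k), b = b)
      })
    })
    kf <- 1 / sqrt(fixed_in)
    P <- H * dirs + Fh
    kh <- 1 / sqrt(P)
    list(ffn = list(W1 = runif_mat(fixed_in, Fh, kf),
                    b1 = stats::runif(Fh, -kf, kf)),
         lstm = lstm,
         head = list(W = runif_mat(P, 1, kh), b = stats::runif(1, -kh, kh)))
  })
}

# Forward pass. `batch` comes from collate(); returns predictions on the
# normalized scale plus the cache needed for backprop. Dropout (inverted,
# per element) is applied between recurrent layers only when training = TRUE.
nn_forward <- function(params, batch, config, training = FALSE) {
  H <- config$hidden_size
  dirs <- if (config$bidirectional) 2L else 1L
  lens <- batch$lens
  B <- length(lens)
  T_max <- length(batch$x)
  if (any(lens < 1L)) stop("sample with zero valid steps", call. = FALSE)

  inp <- batch$x
  layers <- vector("list", config$num_layers)
  drop_masks <- vector("list", config$num_layers)
  for (l in seq_len(config$num_layers)) {
    fwd <- lstm_cell_forward(inp, params$lstm[[l]][[1]]$W,
                             params$lstm[[l]][[1]]$U, params$lstm[[l]][[1]]$b,
                             H)
    if (dirs == 2L) {
      rinp <- reverse_seq(inp, lens)
      bwd <- lstm_cell_forward(rinp, params$lstm[[l]][[2]]$W,
                               params$lstm[[l]][[2]]$U,
                               params$lstm[[l]][[2]]$b, H)
      Hb <- reverse_seq(bwd$H, lens) # align to original time order
      out <- lapply(seq_len(T_max), function(t) cbind(fwd$H[[t]], Hb[[t]]))
      layers[[l]] <- list(fwd = fwd, bwd = bwd, rinp = rinp)
    } else {
      out <- fwd$H
      layers[[l]] <- list(fwd = fwd)
    }
    if (training && config$dropout > 0 && l < config$num_layers) {
      dm <- lapply(out, function(m) {
        matrix(stats::rbinom(length(m), 1, 1 - config$dropout), nrow(m)) /
          (1 - config$dropout)
      })
      out <- Map(`*`, out, dm)
      drop_masks[[l]] <- dm
    }
    inp <- out
  }

  # masked max pooling over time of the top layer's outputs
  D <- H * dirs
  pooled <- matrix(-Inf, B, D)
  argmax <- matrix(0L, B, D)
  for (t in seq_len(T_max)) {
    valid <- lens >= t
    if (!any(valid)) break
    cand <- inp[[t]]
    upd <- valid & (cand > pooled)
    pooled[upd] <- cand[upd]
    argmax[upd] <- t
  }

  z1 <- addb(batch$fixed %*% params$ffn$W1, params$ffn$b1)
  hf <- pmax(z1, 0)
  feat <- cbind(pooled, hf)
  pred <- drop(addb(feat %*% params$head$W, params$head$b))

  list(pred = pred,
       cache = list(layers = layers, top = inp, pooled = pooled,
                    argmax = argmax, z1 = z1, hf = hf, feat = feat,
                    lens = lens, T_max = T_max, dirs = dirs,
                    drop_masks = drop_masks, batch = batch))
}

# Backward pass: gradient of a scalar loss given dpred = dL/dpred.
nn_backward <- function(params, cache, dpred, config) {
  H <- config$hidden_size
  dirs <- cache$dirs
  B <- length(cache$lens)
  D <- H * dirs
  T_max <- cache$T_max

  dpred <- matrix(dpred, ncol = 1)
  g_head <- list(W = crossprod(cache$feat, dpred), b = sum(dpred))
  dfeat <- dpred %*% t(params$head$W)
  dpooled <- dfeat[, seq_len(D), drop = FALSE]
  dhf <- dfeat[, -seq_len(D), drop = FALSE]
  dz1 <- dhf * (cache$z1 > 0)
  g_ffn <- list(W1 = crossprod(cache$batch$fixed, dz1), b1 = colSums(dz1))

  # route pooled gradients to argmax time positions
  dTop <- lapply(seq_len(T_max), function(t) {
    m <- matrix(0, B, D)
    sel <- cache$argmax == t
    m[sel] <- dpooled[sel]
    m
  })

  g_lstm <- vector("list", config$num_layers)
  dOut <- dTop
  for (l in rev(seq_len(config$num_layers))) {
    dm <- cache$drop_masks[[l]]
    if (!is.null(dm)) dOut <- Map(`*`, dOut, dm)
    lay <- cache$layers[[l]]
    pf <- params$lstm[[l]][[1]]
    dFwd <- lapply(dOut, function(m) m[, seq_len(H), drop = FALSE])
    bf <- lstm_cell_backward(dFwd, lay$fwd$cache, pf$W, pf$U)
    g_l <- list(list(W = bf$dW, U = bf$dU, b = bf$db))
    dIn <- bf$dX
    if (dirs == 2L) {
      pb <- params$lstm[[l]][[2]]
      dBwd <- lapply(dOut, function(m) m[, H + seq_len(H), drop = FALSE])
      dBwd_r <- reverse_seq(dBwd, cache$lens)
      bb <- lstm_cell_backward(dBwd_r, lay$bwd$cache, pb$W, pb$U)
      g_l[[2]] <- list(W = bb$dW, U = bb$dU, b = bb$db)
      dIn_b <- reverse_seq(bb$dX, cache$lens)
      dIn <- Map(`+`, dIn, dIn_b)
    }
    g_lstm[[l]] <- g_l
    dOut <- dIn
  }

  list(ffn = g_ffn, lstm = g_lstm, head = g_head)
}

# ---- Adam over nested parameter lists --------------------------------------

tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1L]])) {
    out <- lapply(seq_along(trees[[1L]]), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(trees[[1L]])
    out
  } else {
    do.call(f, trees)
  }
}

adam_init <- function(params) {
  zeros <- function(x) tree_map(function(p) p * 0, x)
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}
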