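# Batched forward and backward passes.
#
# All tensors are base-R arrays; batches are the leading dimension.  The
# backward pass is fully analytic (verified against central finite
# differences in the test suite).  Dropout uses inverted scaling so
# inference needs no correction.

act_forward <- function(z, kind) {
  switch(kind,
    relu = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    tanh = tanh(z)
  )
}

# derivative expressed through the activation output `a`
act_backward <- function(da, a, kind) {
  switch(kind,
    relu = da * (a > 0),
    sigmoid = da * a * (1 - a),
    tanh = da * (1 - a^2)
  )
}

drop_mask <- function(dims, p) {
  if (p <= 0) return(NULL)
  array((runif(prod(dims)) >= p) / (1 - p), dims)
}

# --- convolution (same padding, stride 1) via im2col ------------------------

# A: (N, F, Cin); W: (k, Cin, Cout); returns list(Z = (N, F, Cout), Xcol)
conv_batch_forward <- function(A, W, b) {
  n <- dim(A)[1]; f <- dim(A)[2]; cin <- dim(A)[3]
  k <- dim(W)[1]; cout <- dim(W)[3]
  pad <- (k - 1) %/% 2
  Xcol <- matrix(0, n * f, k * cin)
  for (o in seq_len(k)) {
    src <- seq_len(f) + o - 1 - pad
    ok <- src >= 1 & src <= f
    for (ci in seq_len(cin)) {
      tmp <- matrix(0, n, f)
      tmp[, ok] <- A[, src[ok], ci]
      Xcol[, o + (ci - 1) * k] <- as.vector(tmp)
    }
  }
  Z <- Xcol %*% matrix(W, k * cin, cout)
  Z <- sweep(Z, 2, b, "+")
  list(Z = array(Z, c(n, f, cout)), Xcol = Xcol)
}

conv_batch_backward <- function(dZ, cache, W) {
  n <- dim(dZ)[1]; f <- dim(dZ)[2]; cout <- dim(dZ)[3]
  k <- dim(W)[1]; cin <- dim(W)[2]
  pad <- (k - 1) %/% 2
  dZm <- matrix(dZ, n * f, cout)
  dW <- array(t(cache$Xcol) %*% dZm, c(k, cin, cout))
  db <- colSums(dZm)
  dXcol <- dZm %*% t(matrix(W, k * cin, cout))
  dA <- array(0, c(n, f, cin))
  for (o in seq_len(k)) {
    src <- seq_len(f) + o - 1 - pad
    ok <- src >= 1 & src <= f
    for (ci in seq_len(cin)) {
      tmp <- matrix(dXcol[, o + (ci - 1) * k], n, f)
      dA[, src[ok], ci] <- dA[, src[ok], ci] + tmp[, ok]
    }
  }
  list(dW = dW, db = db, dA = dA)
}

# --- recurrent stage --------------------------------------------------------

# seqs: list of T matrices (N x d).  Returns final hidden state and caches.
rnn_batch_forward <- function(seqs, params, cell, hidden) {
  n <- nrow(seqs[[1]])
  h <- matrix(0, n, hidden)
  cst <- matrix(0, n, hidden)
  steps <- vector("list", length(seqs))
  for (t in seq_along(seqs)) {
    s <- seqs[[t]]
    if (cell == "lstm") {
      g <- s %*% params$rnn_Wx + h %*% params$rnn_Wh
      g <- sweep(g, 2, params$rnn_b, "+")
      i <- sigmoid(g[, seq_len(hidden), drop = FALSE])
      f <- sigmoid(g[, hidden + seq_len(hidden), drop = FALSE])
      cc <- tanh(g[, 2 * hidden + seq_len(hidden), drop = FALSE])
      o <- sigmoid(g[, 3 * hidden + seq_len(hidden), drop = FALSE])
      c_new <- f * cst + i * cc
      h_new <- o * tanh(c_new)
      steps[[t]] <- list(s = s, i = i, f = f, cc = cc, o = o,
                         c_prev = cst, c = c_new, h_prev = h)
      cst <- c_new
      h <- h_new
    } else {
      idx1 <- seq_len(hidden); idx2 <- hidden + idx1; idx3 <- 2 * hidden + idx1
      gz <- s %*% params$rnn_Wx[, c(idx1, idx2), drop = FALSE] +
        h %*% params$rnn_Wh[, c(idx1, idx2), drop = FALSE]
      gz <- sweep(gz, 2, params$rnn_b[c(idx1, idx2)], "+")
      z <- sigmoid(gz[, idx1, drop = FALSE])
      r <- sigmoid(gz[, hidden + idx1, drop = FALSE])
      pre <- s %*% params$rnn_Wx[, idx3, drop = FALSE] +
        (r * h) %*% params$rnn_Wh[, idx3, drop = FALSE]
      pre <- sweep(pre, 2, params$rnn_b[idx3], "+")
      cand <- tanh(pre)
      h_new <- (1 - z) * h + z * cand
      steps[[t]] <- list(s = s, z = z, r = r, cand = cand, h_prev = h)
      h <- h_new
    }
  }
  list(h = h, steps = steps)
}

rnn_batch_backward <- function(dH, cache, params, cell, hidden) {
  steps <- cache$steps
  Tn <- length(steps)
  dWx <- array(0, dim(params$rnn_Wx))
  dWh <- array(0, dim(params$rnn_Wh))
  db <- numeric(length(params$rnn_b))
  dC <- matrix(0, nrow(dH), hidden)
  dSeqs <- vector("list", Tn)
  idx1 <- seq_len(hidden)
  for (t in rev(seq_len(Tn))) {
    st <- steps[[t]]
    if (cell == "lstm") {
      tc <- tanh(st$c)
      do_ <- dH * tc
      dC <- dC + dH * st$o * (1 - tc^2)
      di <- dC * st$cc
      dcc <- dC * st$i
      df <- dC * st$c_prev
      dC_prev <- dC * st$f
      dG <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  dcc * (1 - st$cc^2),
                  do_ * st$o * (1 - st$o))
      dWx <- dWx + t(st$s) %*% dG
      dWh <- dWh + t(st$h_prev) %*% dG
      db <- db + colSums(dG)
      dSeqs[[t]] <- dG %*% t(params$rnn_Wx)
      dH <- dG %*% t(params$rnn_Wh)
      dC <- dC_prev
    } else {
      idx3 <- 2 * hidden + idx1
      dz <- dH * (st$cand - st$h_prev)
      dcand <- dH * st$z
      dh_prev <- dH * (1 - st$z)
      dGc <- dcand * (1 - st$cand^2)
      dWx[, idx3] <- dWx[, idx3] + t(st$s) %*% dGc
      dWh[, idx3] <- dWh[, idx3] + t(st$r * st$h_prev) %*% dGc
      db[idx3] <- db[idx3] + colSums(dGc)
      drh <- dGc %*% t(params$rnn_Wh[, idx3, drop = FALSE])
      dr <- drh * st$h_prev
      dh_prev <- dh_prev + drh * st$r
      dGz <- dz * st$z * (1 - st$z)
      dGr <- dr * st$r * (1 - st$r)
      dGzr <- cbind(dGz, dGr)
      zr <- c(idx1, hidden + idx1)
      dWx[, zr] <- dWx[, zr] + t(st$s) %*% dGzr
      dWh[, zr] <- dWh[, zr] + t(st$h_prev) %*% dGzr
      db[zr] <- db[zr] + colSums(dGzr)
      dSeqs[[t]] <- dGzr %*% t(params$rnn_Wx[, zr, drop = FALSE]) +
        dGc %*% t(params$rnn_Wx[, idx3, drop = FALSE])
      dH <- dh_prev + dGzr %*% t(params$rnn_Wh[, zr, drop = FALSE])
      dC <- dC  # unused for GRU
    }
  }
  list(dWx = dWx, dWh = dWh, db = db, dSeqs = dSeqs)
}

# chunk an (N, F, C) map (or N x F matrix as C = 1) into `t` equal segments,
# zero-padding the position axis; returns list of t matrices (N x seg_len*C)
chunk_sequence <- function(map, t_steps, seg_len) {
  if (length(dim(map)) == 2) map <- array(map, c(dim(map), 1L))
  n <- dim(map)[1]; f <- dim(map)[2]; ch <- dim(map)[3]
  f_pad <- seg_len * t_steps
  if (f_pad > f) {
    padded <- array(0, c(n, f_pad, ch))
    padded[, seq_len(f), ] <- map
    map <- padded
  }
  lapply(seq_len(t_steps), function(s) {
    seg <- map[, (s - 1) * seg_len + seq_len(seg_len), , drop = FALSE]
    matrix(seg, n, seg_len * ch)
  })
}

unchunk_gradient <- function(dSeqs, n, f, ch, seg_len) {
  t_steps <- length(dSeqs)
  dMap <- array(0, c(n, seg_len * t_steps, ch))
  for (s in seq_len(t_steps)) {
    dMap[, (s - 1) * seg_len + seq_len(seg_len), ] <-
      array(dSeqs[[s]], c(n, seg_len, ch))
  }
  dMap[, seq_len(f), , drop = FALSE]
}

# --- full network -----------------------------------------------------------

# X: N x F matrix.  Returns probs, logits and caches for backprop.
nn_forward <- function(params, config, X, training = FALSE) {
  d <- config_dims(config)
  n <- nrow(X)
  p <- if (training) config$dropout else 0
  act <- config$activation
  cache <- list(X = X, masks = list())

  feat <- NULL
  if (config$use_cnn) {
    A <- array(X, c(n, d$f_in, 1L))
    conv_caches <- list()
    for (i in seq_along(config$conv_channels)) {
      cv <- conv_batch_forward(A, params[[paste0("conv", i, "_W")]],
                               params[[paste0("conv", i, "_b")]])
      # dropout is reserved for the dense stages; dropping units of the small
      # convolution maps at p = 0.5 destabilizes training badly
      Aact <- act_forward(cv$Z, act)
      conv_caches[[i]] <- list(Xcol = cv$Xcol, Aact = Aact, Z = cv$Z, mask = NULL)
      A <- Aact
    }
    cache$conv <- conv_caches
    feat <- A  # (N, F, C_last)
  }

  if (config$use_lstm) {
    src <- if (config$use_cnn) feat else X
    seqs <- chunk_sequence(src, config$seq_len, d$seg_len)
    rnn <- rnn_batch_forward(seqs, params, config$recurrent_cell,
                             config$hidden_size)
    cache$rnn <- rnn
    cache$seq_src_dim <- if (config$use_cnn) d$c_last else 1L
    # the projection aggregates the conv features and the recurrent state
    z <- if (config$use_cnn) {
      cbind(matrix(feat, n, d$f_in * d$c_last), rnn$h)
    } else {
      rnn$h
    }
  } else if (config$use_cnn) {
    z <- matrix(feat, n, d$f_in * d$c_last)
  } else {
    Zm <- sweep(X %*% params$mlp_W, 2, params$mlp_b, "+")
    Araw <- act_forward(Zm, act)
    cache$mlp <- list(Araw = Araw)
    z <- Araw
  }
  # one dropout layer on the aggregated representation entering the
  # projection, identical for every variant
  mask_z <- drop_mask(dim(z), p)
  if (!is.null(mask_z)) z <- z * mask_z
  cache$z_mask <- mask_z
  cache$z <- z

  Zp <- sweep(z %*% params$proj_W, 2, params$proj_b, "+")
  XLraw <- act_forward(Zp, act)
  mask_p <- drop_mask(dim(XLraw), p)
  XL <- if (is.null(mask_p)) XLraw else XLraw * mask_p
  cache$proj <- list(XL = XL, XLraw = XLraw, mask = mask_p)

  ft <- config$feature_dim
  if (config$use_topology) {
    if (config$topology_mode == "learned") {
      S <- XL %*% params$topo_W                    # N x ft^2, col = i + (j-1)*ft
      Aflat <- pmax(S, 0)
      refined <- matrix(0, n, ft)
      for (i in seq_len(ft)) {
        idx <- i + (seq_len(ft) - 1L) * ft
        refined[, i] <- rowSums(Aflat[, idx, drop = FALSE] * XL)
      }
      cache$topo <- list(S = S, Aflat = Aflat)
    } else {
      Acorr <- if (n >= 2) {
        suppressWarnings(topology_adjacency(XL, mode = "correlation"))
      } else {
        diag(ft)
      }
      refined <- XL %*% Acorr                      # A symmetric
      cache$topo <- list(Acorr = Acorr)
    }
    U <- cbind(refined, XL)
  } else {
    U <- XL
  }
  cache$U <- U

  logits <- sweep(U %*% params$out_W, 2, params$out_b, "+")
  probs <- softmax(logits)
  list(probs = probs, logits = logits, cache = cache)
}

# Gradients of mean cross-entropy (+ L2 handled by the caller) w.r.t. every
# parameter.  `y` are integer class codes 1..K.
nn_backward <- function(params, config, fw, y) {
  d <- config_dims(config)
  cache <- fw$cache
  n <- nrow(cache$X)
  act <- config$activation
  ft <- config$feature_dim
  grads <- list()

  dLogits <- fw$probs
  dLogits[cbind(seq_len(n), y)] <- dLogits[cbind(seq_len(n), y)] - 1
  dLogits <- dLogits / n

  grads$out_W <- t(cache$U) %*% dLogits
  grads$out_b <- colSums(dLogits)
  dU <- dLogits %*% t(params$out_W)

  XL <- cache$proj$XL
  if (config$use_topology) {
    dRef <- dU[, seq_len(ft), drop = FALSE]
    dXL <- dU[, ft + seq_len(ft), drop = FALSE]
    if (config$topology_mode == "learned") {
      Aflat <- cache$topo$Aflat
      dAflat <- matrix(0, n, ft * ft)
      for (i in seq_len(ft)) {
        idx <- i + (seq_len(ft) - 1L) * ft
        dAflat[, idx] <- dRef[, i] * XL
        dXL <- dXL + Aflat[, idx, drop = FALSE] * dRef[, i]
      }
      dS <- dAflat * (cache$topo$S > 0)
      grads$topo_W <- t(XL) %*% dS
      dXL <- dXL + dS %*% t(params$topo_W)
    } else {
      # adjacency treated as constant (stop-gradient)
      dXL <- dXL + dRef %*% t(cache$topo$Acorr)
    }
  } else {
    dXL <- dU
  }

  if (!is.null(cache$proj$mask)) dXL <- dXL * cache$proj$mask
  dZp <- act_backward(dXL, cache$proj$XLraw, act)
  grads$proj_W <- t(cache$z) %*% dZp
  grads$proj_b <- colSums(dZp)
  dz <- dZp %*% t(params$proj_W)

  if (!is.null(cache$z_mask)) dz <- dz * cache$z_mask
  if (config$use_lstm) {
    if (config$use_cnn) {
      flat <- d$f_in * d$c_last
      dz_conv <- dz[, seq_len(flat), drop = FALSE]
      dh <- dz[, flat + seq_len(config$hidden_size), drop = FALSE]
    } else {
      dz_conv <- NULL
      dh <- dz
    }
    rb <- rnn_batch_backward(dh, cache$rnn, params, config$recurrent_cell,
                             config$hidden_size)
    grads$rnn_Wx <- rb$dWx
    grads$rnn_Wh <- rb$dWh
    grads$rnn_b <- rb$db
    if (config$use_cnn) {
      dFeat <- unchunk_gradient(rb$dSeqs, n, d$f_in, d$c_last, d$seg_len) +
        array(dz_conv, c(n, d$f_in, d$c_last))
      grads <- conv_chain_backward(params, config, cache, dFeat, grads, act)
    }
  } else if (config$use_cnn) {
    dFeat <- array(dz, c(n, d$f_in, d$c_last))
    grads <- conv_chain_backward(params, config, cache, dFeat, grads, act)
  } else {
    dZm <- act_backward(dz, cache$mlp$Araw, act)
    grads$mlp_W <- t(cache$X) %*% dZm
    grads$mlp_b <- colSums(dZm)
  }
  grads
}

conv_chain_backward <- function(params, config, cache, dOut, grads, act) {
  n_layers <- length(config$conv_channels)
  dA <- dOut
  for (i in rev(seq_len(n_layers))) {
    cc <- cache$conv[[i]]
    if (!is.null(cc$mask)) dA <- dA * cc$mask
    dZ <- act_backward(dA, act_forward(cc$Z, act), act)
    bk <- conv_batch_backward(dZ, cc, params[[paste0("conv", i, "_W")]])
    grads[[paste0("conv", i, "_W")]] <- bk$dW
    grads[[paste0("conv", i, "_b")]] <- bk$db
    dA <- bk$dA
  }
  grads
}
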