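# Network building blocks: convolution, activations, recurrence, topology
# adjacency, softmax head, variant configs, and analytic-gradient checks.

test_that("1-D convolution matches hand-computed values", {
  # zero kernel and bias annihilate the input
  expect_equal(conv1d_forward(c(1, 2, 3), c(0, 0, 0)), c(0, 0, 0))

  # hand summation: 1*1 + 2*0 + 3*(-1) = -2
  expect_equal(conv1d_forward(c(1, 2, 3), c(1, 0, -1), padding = "valid"), -2)

  # identity kernel reproduces the input under same padding
  x <- c(4, -1, 2.5, 0, 7)
  expect_equal(conv1d_forward(x, c(0, 1, 0)), x)

  # bias is added per output channel
  expect_equal(conv1d_forward(c(1, 2, 3), c(1, 0, -1), b = 10, padding = "valid"), 8)

  expect_error(conv1d_forward(c(1, 2), c(1, 1, 1), padding = "valid"), "exceeds")
  w2 <- array(1, c(3, 2, 1))
  expect_error(conv1d_forward(c(1, 2, 3), w2), "channel")
})

test_that("activations implement their definitions", {
  expect_equal(activate(c(-1, 2), "relu"), c(0, 2))
  expect_equal(activate(0, "sigmoid"), 0.5)
  expect_equal(activate(0, "tanh"), 0)
  expect_equal(activate(matrix(c(-1, 1), 1), "tanh"), matrix(tanh(c(-1, 1)), 1))
  expect_error(activate(0, "swish"), "unknown")
})

test_that("recurrent forward matches a hand-computed one-step LSTM", {
  # zero parameters and inputs give a zero hidden state
  p0 <- list(W_x = matrix(0, 2, 8), W_h = matrix(0, 2, 8), b = rep(0, 8))
  expect_equal(recurrent_forward(matrix(0, 3, 2), p0), c(0, 0))

  # scalar LSTM, one step, hand evaluation of the gate equations
  wx <- c(0.5, -0.3, 0.8, 0.2)   # input, forget, cell, output
  p <- list(W_x = matrix(wx, 1, 4), W_h = matrix(0, 1, 4), b = rep(0.1, 4))
  s <- 0.7
  i <- 1 / (1 + exp(-(0.5 * s + 0.1)))
  f <- 1 / (1 + exp(-(-0.3 * s + 0.1)))
  g <- tanh(0.8 * s + 0.1)
  o <- 1 / (1 + exp(-(0.2 * s + 0.1)))
  expect_equal(recurrent_forward(matrix(s, 1, 1), p), o * tanh(i * g),
               tolerance = 1e-12)

  # hidden length equals the configured size for any input length
  set.seed(1)
  p4 <- list(W_x = matrix(rnorm(3 * 16), 3), W_h = matrix(rnorm(4 * 16), 4),
             b = rnorm(16))
  for (steps in c(1, 2, 7)) {
    expect_length(recurrent_forward(matrix(rnorm(steps * 3), steps), p4), 4)
  }
  expect_error(recurrent_forward(matrix(0, 0, 2), p0), "empty")

  # GRU with zero parameters also stays at zero
  pg <- list(W_x = matrix(0, 2, 6), W_h = matrix(0, 2, 6), b = rep(0, 6))
  expect_equal(recurrent_forward(matrix(1, 2, 2), pg, cell = "gru"), c(0, 0))
})

test_that("topology adjacency honours the ReLU image and correlation limits", {
  f <- 3
  w <- array(rnorm(f * f * f), c(f, f, f))
  expect_equal(topology_adjacency(rep(0, f), w), matrix(0, f, f))

  w_neg <- array(-abs(rnorm(f * f * f)), c(f, f, f))
  a <- topology_adjacency(rep(1, f), w_neg)
  expect_equal(a, matrix(0, f, f))
  expect_true(all(topology_adjacency(rnorm(f), w) >= 0))

  # learned-mode entries follow a_ij = relu(w_ij . x) exactly
  x <- c(0.3, -0.2, 0.9)
  a2 <- topology_adjacency(x, w)
  expect_equal(a2[2, 3], max(0, sum(w[2, 3, ] * x)))

  # perfectly proportional features have |correlation| 1
  set.seed(2)
  xm <- cbind(a = rnorm(20), b = 0, c = rnorm(20))
  xm[, "b"] <- 2 * xm[, "a"]
  ac <- topology_adjacency(xm, mode = "correlation")
  expect_equal(ac[1, 2], 1)
  expect_equal(diag(ac), rep(1, 3))

  # zero-variance feature zeroes its row/column but keeps the diagonal
  xm2 <- cbind(rnorm(10), 5, rnorm(10))
  expect_warning(az <- topology_adjacency(xm2, mode = "correlation"),
                 "zero-variance")
  expect_equal(az[2, c(1, 3)], c(0, 0))
  expect_equal(az[2, 2], 1)
  expect_error(topology_adjacency(xm2[1, , drop = FALSE], mode = "correlation"),
               ">= 2")
})

test_that("the softmax head is a proper probability map", {
  k <- 4; f <- 3
  # zero logits give the uniform distribution
  expect_equal(classify(rnorm(f), NULL, matrix(0, k, f), rep(0, k)),
               rep(1 / k, k))

  # two-class closed form e/(e+1)
  w <- rbind(c(1, 0), c(0, 0))
  p <- classify(c(1, 1), NULL, matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE), c(0, 0))
  expect_equal(round(p, 4), c(0.7311, 0.2689))

  # normalization and positivity across random parameter draws
  set.seed(3)
  for (rep in 1:200) {
    a <- matrix(abs(rnorm(f * f)), f)
    pr <- classify(rnorm(f), a, matrix(rnorm(k * 2 * f), k), rnorm(k))
    expect_true(all(pr > 0))
    expect_lt(abs(sum(pr) - 1), 1e-9)
  }
  expect_error(classify(rnorm(3), NULL, matrix(0, 2, 5), c(0, 0)), "columns")
})

test_that("build_variant sets exactly the documented stage toggles", {
  toggles <- list(
    full = c(TRUE, TRUE, TRUE), cnn_only = c(TRUE, FALSE, FALSE),
    cnn_lstm = c(TRUE, TRUE, FALSE), cnn_topology = c(TRUE, FALSE, TRUE),
    lstm_only = c(FALSE, TRUE, FALSE), mlp_only = c(FALSE, FALSE, FALSE)
  )
  for (nm in names(toggles)) {
    cfg <- build_variant(nm, n_features = 10, n_classes = 4)
    expect_equal(c(cfg$use_cnn, cfg$use_lstm, cfg$use_topology),
                 toggles[[nm]], info = nm)
    expect_equal(cfg$variant, nm)
  }
  expect_error(build_variant("resnet", 10, 4), "unknown variant")
  expect_error(model_config(10, 1), "n_classes")
  expect_error(model_config(10, 4, dropout = 1), "dropout")
})

test_that("forward pass is deterministic with dropout disabled", {
  cfg <- tiny_config()
  st <- init_model(cfg, seed = 5)
  x <- with_seed_test(6, matrix(runif(40 * 7), 40))
  p1 <- aidnet:::nn_forward(unclass(st), cfg, x)$probs
  p2 <- aidnet:::nn_forward(unclass(st), cfg, x)$probs
  expect_identical(p1, p2)
  expect_true(all(abs(rowSums(p1) - 1) < 1e-9))
})

test_that("zeroing topology weights collapses the full model onto cnn_lstm", {
  full_cfg <- tiny_config()
  red_cfg <- tiny_config(use_topology = FALSE)
  full <- unclass(init_model(full_cfg, seed = 7))
  full$topo_W[] <- 0
  reduced <- full[setdiff(names(full), "topo_W")]
  ft <- full_cfg$feature_dim
  reduced$out_W <- full$out_W[ft + seq_len(ft), , drop = FALSE]
  x <- with_seed_test(8, matrix(runif(15 * 7), 15))
  lf <- aidnet:::nn_forward(full, full_cfg, x)$logits
  lr <- aidnet:::nn_forward(reduced, red_cfg, x)$logits
  expect_equal(lf, lr, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  # smooth activations keep finite differences away from ReLU kinks
  expect_lt(max_gradient_error(tiny_config(activation = "tanh")), 1e-7)
  expect_lt(max_gradient_error(tiny_config(activation = "sigmoid")), 1e-7)
  expect_lt(max_gradient_error(
    tiny_config(activation = "tanh", use_lstm = FALSE)), 1e-7)
  expect_lt(max_gradient_error(
    tiny_config(activation = "tanh", use_cnn = FALSE, use_topology = FALSE,
                dense_units = 5L)), 1e-7)
  expect_lt(max_gradient_error(
    tiny_config(activation = "tanh", recurrent_cell = "gru")), 1e-7)
})
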