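# Elementary network operations exposed as standalone functions: 1-D
# convolution, element-wise activations, gated recurrence, the graph
# topology adjacency, and the fused softmax head.  The batched training
# path (model-forward.R) reuses the same arithmetic.

#' 1-D convolution (cross-correlation) over a feature signal
#'
#' Slides each kernel across the input with stride 1 and adds a per-channel
#' bias.  `"same"` padding zero-pads so the output length equals the input
#' length; `"valid"` keeps only fully overlapping positions.
#'
#' @param x Numeric vector (single-channel signal) or a `length x channels`
#'   matrix.
#' @param w Kernel: a numeric vector (single in/out channel) or an array of
#'   shape `(kernel, in_channels, out_channels)`.
#' @param b Bias, one value per output channel (default 0).
#' @param padding `"same"` (default) or `"valid"`.
#' @return A `positions x out_channels` matrix of pre-activations (dropped
#'   to a vector for a single output channel).
#' @examples
#' conv1d_forward(c(1, 2, 3), c(1, 0, -1), padding = "valid")  # -2
#' @export
conv1d_forward <- function(x, w, b = 0, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (is.vector(w)) w <- array(w, c(length(w), 1, 1))
  if (length(dim(w)) != 3) stop("`w` must be a (kernel, in, out) array or a vector")
  k <- dim(w)[1]; cin <- dim(w)[2]; cout <- dim(w)[3]
  if (ncol(x) != cin) {
    stop("input has ", ncol(x), " channel(s) but kernel expects ", cin)
  }
  len <- nrow(x)
  if (padding == "same") {
    pad <- (k - 1) %/% 2
    padded <- rbind(matrix(0, pad, cin), x, matrix(0, k - 1 - pad, cin))
    npos <- len
  } else {
    if (k > len) stop("kernel length ", k, " exceeds input length ", len)
    padded <- x
    npos <- len - k + 1
  }
  b <- rep_len(b, cout)
  out <- matrix(0, npos, cout)
  for (co in seq_len(cout)) {
    acc <- rep(b[co], npos)
    for (ci in seq_len(cin)) {
      for (o in seq_len(k)) {
        acc <- acc + padded[(o - 1) + seq_len(npos), ci] * w[o, ci, co]
      }
    }
    out[, co] <- acc
  }
  if (cout == 1) drop(out) else out
}

#' Element-wise activation
#'
#' @param z Numeric vector, matrix or array of pre-activations.
#' @param kind One of `"relu"`, `"sigmoid"`, `"tanh"`.
#' @return Activations with the shape of `z` preserved.
#' @export
activate <- function(z, kind = c("relu", "sigmoid", "tanh")) {
  if (!is.character(kind) || !kind[1] %in% c("relu", "sigmoid", "tanh")) {
    stop("unknown activation kind: ", kind[1])
  }
  switch(kind[1],
    relu = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    tanh = tanh(z)
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Gated recurrent forward pass over a sequence
#'
#' Runs a standard LSTM (input/forget/cell/output gates) or GRU over a
#' sequence of feature vectors and returns the final hidden state.
#'
#' @param sequence A `T x d` matrix (rows are time steps) or a list of
#'   length-`d` vectors.
#' @param params List with `W_x` (`d x 4H` for LSTM, `d x 3H` for GRU),
#'   `W_h` (`H x 4H` / `H x 3H`) and `b` (length `4H` / `3H`).  Gate order
#'   is input, forget, cell, output (LSTM) and update, reset, candidate
#'   (GRU).
#' @param cell `"lstm"` (default) or `"gru"`.
#' @return The final hidden state, length `H`.
#' @export
recurrent_forward <- function(sequence, params, cell = c("lstm", "gru")) {
  cell <- match.arg(cell)
  if (is.list(sequence) && !is.data.frame(sequence)) {
    sequence <- do.call(rbind, sequence)
  }
  sequence <- as.matrix(sequence)
  if (nrow(sequence) == 0) stop("empty sequence")
  gates <- if (cell == "lstm") 4L else 3L
  H <- ncol(params$W_h)
  if (H %% gates != 0) stop("recurrent parameter shapes inconsistent")
  H <- H / gates
  h <- matrix(0, 1, H)
  cst <- matrix(0, 1, H)
  for (t in seq_len(nrow(sequence))) {
    s <- matrix(sequence[t, ], 1)
    if (cell == "lstm") {
      g <- s %*% params$W_x + h %*% params$W_h + rep(params$b, each = 1)
      i <- sigmoid(g[, seq_len(H), drop = FALSE])
      f <- sigmoid(g[, H + seq_len(H), drop = FALSE])
      cc <- tanh(g[, 2 * H + seq_len(H), drop = FALSE])
      o <- sigmoid(g[, 3 * H + seq_len(H), drop = FALSE])
      cst <- f * cst + i * cc
      h <- o * tanh(cst)
    } else {
      gz <- s %*% params$W_x[, seq_len(2 * H), drop = FALSE] +
        h %*% params$W_h[, seq_len(2 * H), drop = FALSE]
      gz <- sweep(gz, 2, params$b[seq_len(2 * H)], "+")
      z <- sigmoid(gz[, seq_len(H), drop = FALSE])
      r <- sigmoid(gz[, H + seq_len(H), drop = FALSE])
      cand <- tanh(s %*% params$W_x[, 2 * H + seq_len(H), drop = FALSE] +
                   (r * h) %*% params$W_h[, 2 * H + seq_len(H), drop = FALSE] +
                   matrix(params$b[2 * H + seq_len(H)], 1))
      h <- (1 - z) * h + z * cand
    }
  }
  drop(h)
}

#' Feature-topology adjacency matrix
#'
#' Learned mode realizes `a_ij = ReLU(w_ij . x)`: one weight vector per
#' ordered feature pair, applied to the activation vector.  Correlation mode
#' sets `a_ij` to the absolute Pearson correlation of features `i` and `j`
#' across the batch, with unit diagonal; zero-variance features yield zero
#' rows/columns (diagonal kept at 1) with a warning.
#'
#' @param x Learned mode: a numeric activation vector of length `F`.
#'   Correlation mode: an `n x F` matrix with `n >= 2`.
#' @param w Learned mode only: an `(F, F, F)` array; `w[i, j, ]` is the
#'   weight vector for the pair `(i, j)`.
#' @param mode `"learned"` (default) or `"correlation"`.
#' @return An `F x F` non-negative adjacency matrix.
#' @export
topology_adjacency <- function(x, w = NULL, mode = c("learned", "correlation")) {
  mode <- match.arg(mode)
  if (mode == "learned") {
    x <- as.numeric(x)
    if (is.null(w)) stop("learned mode requires pair weights `w`")
    f <- dim(w)[1]
    if (dim(w)[2] != f || dim(w)[3] != length(x)) {
      stop("`w` must be an (F, F, length(x)) array")
    }
    a <- matrix(0, f, f)
    for (j in seq_len(f)) {
      wj <- matrix(w[, j, ], nrow = f, ncol = length(x))
      a[, j] <- pmax(as.numeric(wj %*% x), 0)
    }
    a
  } else {
    x <- as.matrix(x)
    if (nrow(x) < 2) stop("correlation mode needs >= 2 rows")
    sds <- apply(x, 2, sd)
    flat <- sds == 0 | is.na(sds)
    a <- matrix(0, ncol(x), ncol(x))
    if (any(!flat)) {
      a[!flat, !flat] <- abs(cor(x[, !flat, drop = FALSE]))
    }
    if (any(flat)) {
      warning(sum(flat), " zero-variance feature(s); adjacency rows/columns zeroed")
    }
    diag(a) <- 1
    a
  }
}

#' Fused softmax classification head
#'
#' Refines the extracted features through the adjacency (`A %*% x`),
#' concatenates the refined features with the extracted features themselves,
#' and applies an affine map followed by softmax.
#'
#' @param x_l Extracted feature vector (length `F`).
#' @param a `F x F` adjacency matrix, or `NULL` when topology refinement is
#'   disabled (the head then acts on `x_l` alone).
#' @param w_out `K x F` (no topology) or `K x 2F` (with topology) output
#'   weight matrix.
#' @param b_out Length-`K` output bias.
#' @return Length-`K` probability vector (positive, sums to 1).
#' @export
classify <- function(x_l, a = NULL, w_out, b_out) {
  x_l <- as.numeric(x_l)
  u <- if (is.null(a)) x_l else c(as.numeric(a %*% x_l), x_l)
  if (ncol(w_out) != length(u)) {
    stop("`w_out` has ", ncol(w_out), " columns but head input has length ",
         length(u))
  }
  softmax(as.numeric(w_out %*% u + b_out))
}

# Numerically-stable softmax; matrix rows are treated as samples.
softmax <- function(z) {
  if (is.matrix(z)) {
    z <- z - apply(z, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}
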