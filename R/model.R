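# Model configuration, ablation variants and Xavier initialization.
#
# The network stacks five learnable stages: two 1-D convolutional layers
# over the preprocessed feature vector (treated as a length-F single-channel
# signal), a gated recurrent stage over ordered segments of the convolution
# map, a dense projection to a compact extracted-feature vector, and the
# softmax output head (optionally fused with graph-topology-refined
# features).  Ablation variants toggle the convolutional, recurrent and
# topology stages while sharing every other hyperparameter.

AID_VARIANTS <- c("full", "cnn_only", "cnn_lstm", "cnn_topology",
                  "lstm_only", "mlp_only")

#' Declarative model configuration
#'
#' @param n_features Length of the preprocessed input feature vector.
#' @param n_classes Number of disease classes `K` (>= 2).
#' @param use_cnn,use_lstm,use_topology Stage toggles; all three `FALSE`
#'   gives the dense-only (MLP) variant.
#' @param kernel_size Odd convolution kernel length.
#' @param conv_channels Output channels of the successive conv layers.
#' @param hidden_size Hidden size of the recurrent stage.
#' @param seq_len Number of ordered segments the convolution map (or the raw
#'   feature vector, without CNN) is chunked into to form the recurrent
#'   input sequence; multi-visit data supply their own sequence instead.
#' @param feature_dim Size of the extracted-feature vector entering the
#'   topology stage and the head.
#' @param dense_units Hidden width of the dense stage in the MLP-only
#'   variant.
#' @param dropout Dropout probability `p` in `[0, 1)`, applied after each
#'   hidden activation during training.
#' @param activation Hidden activation kind: `"relu"`, `"sigmoid"` or
#'   `"tanh"`.
#' @param topology_mode `"learned"` (per-pair weight vectors, Eq.-style
#'   `ReLU(w_ij . x)`) or `"correlation"` (absolute batch Pearson
#'   correlation, treated as constant during backpropagation).
#' @param recurrent_cell `"lstm"` (default) or `"gru"`.
#' @param variant Optional variant label carried for reporting.
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(n_features, n_classes,
                         use_cnn = TRUE, use_lstm = TRUE, use_topology = TRUE,
                         kernel_size = 3L, conv_channels = c(8L, 16L),
                         hidden_size = 32L, seq_len = 3L,
                         feature_dim = 16L, dense_units = 64L,
                         dropout = 0.5, activation = "relu",
                         topology_mode = c("learned", "correlation"),
                         recurrent_cell = c("lstm", "gru"),
                         variant = NULL) {
  topology_mode <- match.arg(topology_mode)
  recurrent_cell <- match.arg(recurrent_cell)
  if (n_classes < 2) stop("`n_classes` must be >= 2")
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)")
  if (kernel_size %% 2 != 1) stop("`kernel_size` must be odd")
  if (!activation %in% c("relu", "sigmoid", "tanh")) {
    stop("unknown activation: ", activation)
  }
  cfg <- list(
    n_features = as.integer(n_features), n_classes = as.integer(n_classes),
    use_cnn = isTRUE(use_cnn), use_lstm = isTRUE(use_lstm),
    use_topology = isTRUE(use_topology),
    kernel_size = as.integer(kernel_size),
    conv_channels = as.integer(conv_channels),
    hidden_size = as.integer(hidden_size), seq_len = as.integer(seq_len),
    feature_dim = as.integer(feature_dim), dense_units = as.integer(dense_units),
    dropout = dropout, activation = activation,
    topology_mode = topology_mode, recurrent_cell = recurrent_cell,
    variant = variant %||% "custom"
  )
  class(cfg) <- "model_config"
  cfg
}

#' Build the configuration of a named ablation variant
#'
#' The six variants toggle the convolutional, recurrent and topology stages:
#' `full` (CNN + LSTM + topology), `cnn_only`, `cnn_lstm` (no topology),
#' `cnn_topology` (no LSTM), `lstm_only`, and `mlp_only` (dense layers
#' only).  All other hyperparameters are shared across variants.
#'
#' @param name One of `"full"`, `"cnn_only"`, `"cnn_lstm"`,
#'   `"cnn_topology"`, `"lstm_only"`, `"mlp_only"`.
#' @param n_features,n_classes Input/output dimensions.
#' @param ... Further arguments passed to [model_config()].
#' @return A `"model_config"`.
#' @export
build_variant <- function(name, n_features, n_classes, ...) {
  if (!name %in% AID_VARIANTS) {
    stop("unknown variant `", name, "`; expected one of: ",
         paste(AID_VARIANTS, collapse = ", "))
  }
  toggles <- switch(name,
    full         = c(TRUE,  TRUE,  TRUE),
    cnn_only     = c(TRUE,  FALSE, FALSE),
    cnn_lstm     = c(TRUE,  TRUE,  FALSE),
    cnn_topology = c(TRUE,  FALSE, TRUE),
    lstm_only    = c(FALSE, TRUE,  FALSE),
    mlp_only     = c(FALSE, FALSE, FALSE)
  )
  model_config(n_features = n_features, n_classes = n_classes,
               use_cnn = toggles[1], use_lstm = toggles[2],
               use_topology = toggles[3], variant = name, ...)
}

#' @export
print.model_config <- function(x, ...) {
  stages <- c(
    if (x$use_cnn) paste0("conv[", paste(x$conv_channels, collapse = ","),
                          " ch, k=", x$kernel_size, "]"),
    if (x$use_lstm) paste0(x$recurrent_cell, "[", x$hidden_size, "]"),
    if (!x$use_cnn && !x$use_lstm) paste0("dense[", x$dense_units, "]"),
    paste0("proj[", x$feature_dim, "]"),
    if (x$use_topology) paste0("topology[", x$topology_mode, "]"),
    paste0("softmax[", x$n_classes, "]")
  )
  cat("Model config (", x$variant, "): ", x$n_features, " features -> ",
      paste(stages, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

# Derived layer dimensions shared by init/forward/backward.
config_dims <- function(config) {
  f_in <- config$n_features
  c_last <- if (config$use_cnn) config$conv_channels[length(config$conv_channels)] else 1L
  d <- list(f_in = f_in, c_last = c_last)
  if (config$use_lstm) {
    positions <- f_in
    d$seg_len <- as.integer(ceiling(positions / config$seq_len))
    d$f_pad <- d$seg_len * config$seq_len
    d$step_dim <- d$seg_len * c_last
  }
  # the dense projection aggregates every extracted representation: the
  # flattened convolution map, the recurrent state, or the MLP hidden layer
  d$z_dim <- if (config$use_cnn && config$use_lstm) {
    f_in * c_last + config$hidden_size
  } else if (config$use_lstm) {
    config$hidden_size
  } else if (config$use_cnn) {
    f_in * c_last
  } else {
    config$dense_units
  }
  d$u_dim <- config$feature_dim * (if (config$use_topology) 2L else 1L)
  d
}

xavier <- function(dims, fan_in, fan_out) {
  bound <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -bound, bound), dims)
}

#' Initialize model weights (Xavier-uniform)
#'
#' Weights are drawn uniformly on `+/- sqrt(6 / (fan_in + fan_out))` per
#' tensor; biases start at zero.  Seeded and reproducible.
#'
#' @param config A [model_config()].
#' @param seed RNG seed.
#' @return A named list of parameter arrays of class `"model_state"`, with
#'   the initialization seed stored as an attribute.
#' @export
init_model <- function(config, seed = 1L) {
  d <- config_dims(config)
  k <- config$kernel_size
  p <- list()
  with_seed(seed, {
    if (config$use_cnn) {
      cin <- 1L
      for (i in seq_along(config$conv_channels)) {
        cout <- config$conv_channels[i]
        p[[paste0("conv", i, "_W")]] <- xavier(c(k, cin, cout), k * cin, k * cout)
        p[[paste0("conv", i, "_b")]] <- numeric(cout)
        cin <- cout
      }
    }
    if (config$use_lstm) {
      gates <- if (config$recurrent_cell == "lstm") 4L else 3L
      h <- config$hidden_size
      p$rnn_Wx <- xavier(c(d$step_dim, gates * h), d$step_dim, gates * h)
      p$rnn_Wh <- xavier(c(h, gates * h), h, gates * h)
      p$rnn_b <- numeric(gates * h)
      if (config$recurrent_cell == "lstm") {
        p$rnn_b[h + seq_len(h)] <- 1  # forget gate opens at init (standard)
      }
    }
    if (!config$use_cnn && !config$use_lstm) {
      p$mlp_W <- xavier(c(d$f_in, config$dense_units), d$f_in, config$dense_units)
      p$mlp_b <- numeric(config$dense_units)
    }
    p$proj_W <- xavier(c(d$z_dim, config$feature_dim), d$z_dim, config$feature_dim)
    p$proj_b <- numeric(config$feature_dim)
    if (config$use_topology && config$topology_mode == "learned") {
      ft <- config$feature_dim
      p$topo_W <- xavier(c(ft, ft * ft), ft, ft * ft)
    }
    p$out_W <- xavier(c(d$u_dim, config$n_classes), d$u_dim, config$n_classes)
    p$out_b <- numeric(config$n_classes)
  })
  structure(p, class = "model_state", seed = as.integer(seed))
}

#' Count model parameters
#' @param state A `"model_state"`.
#' @return Total number of scalar parameters.
#' @export
n_parameters <- function(state) {
  sum(vapply(state, length, numeric(1)))
}

#' Save / load a trained model archive
#'
#' Serializes the fitted object to an RDS archive alongside a JSON manifest
#' recording parameter shapes and the initialization seed.
#'
#' @param object A fitted `"aidnet"` model (or any R object).
#' @param path Archive path (`.rds`); the manifest is written next to it
#'   with extension `.manifest.json`.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   restored object.
#' @export
write_model <- function(object, path) {
  saveRDS(object, path)
  state <- if (inherits(object, "aidnet")) object$state else object
  manifest <- list(
    class = class(object)[1],
    init_seed = attr(state, "seed"),
    shapes = lapply(state, function(w) dim(w) %||% length(w))
  )
  jsonlite::write_json(manifest, sub("\\.rds$", ".manifest.json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  readRDS(path)
}
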