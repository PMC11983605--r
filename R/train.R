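# Supervised training: cross-entropy objective with L2 weight decay,
# Adam or SGD-with-momentum, seeded mini-batching and early stopping on
# validation loss with restore-best-weights semantics.

#' Training hyperparameters
#'
#' Defaults follow the study protocol: learning rate 0.001, batch size 64,
#' 100 epochs, dropout 0.5, L2 coefficient 0.0001, Adam optimizer, 10%
#' validation monitoring with early stopping (patience 10 epochs).
#'
#' @param learning_rate Step size `eta` (> 0).
#' @param batch_size Mini-batch size `B` (>= 1); the last incomplete batch
#'   is kept.
#' @param epochs Maximum epoch count `E` (>= 0).
#' @param dropout Dropout probability `p` handed to the model config.
#' @param l2 L2 coefficient `lambda` (>= 0); the objective is
#'   `cross-entropy + lambda * sum(weights^2)` (biases excluded).
#' @param optimizer `"adam"` (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) or
#'   `"sgd_momentum"`.
#' @param momentum SGD momentum coefficient.
#' @param patience Early-stopping patience in epochs (>= 1).
#' @param seed RNG seed for shuffling and dropout.
#' @return An object of class `"hyperparams"`.
#' @export
hyperparams <- function(learning_rate = 0.001, batch_size = 64L,
                        epochs = 100L, dropout = 0.5, l2 = 1e-4,
                        optimizer = c("adam", "sgd_momentum"),
                        momentum = 0.9, patience = 10L, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stop("`learning_rate` must be > 0")
  if (batch_size < 1) stop("`batch_size` must be >= 1")
  if (epochs < 0) stop("`epochs` must be >= 0")
  if (l2 < 0) stop("`l2` must be >= 0")
  if (patience < 1) stop("`patience` must be >= 1")
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), dropout = dropout, l2 = l2,
         optimizer = optimizer, momentum = momentum,
         patience = as.integer(patience), seed = as.integer(seed)),
    class = "hyperparams"
  )
}

#' @export
print.hyperparams <- function(x, ...) {
  cat("Hyperparameters: lr", x$learning_rate, "| batch", x$batch_size,
      "| epochs", x$epochs, "| dropout", x$dropout, "| L2", x$l2,
      "|", x$optimizer, "| patience", x$patience, "\n")
  invisible(x)
}

#' Mean cross-entropy loss
#'
#' Mean of `-log p_true` over samples, in nats.  Probabilities at the true
#' class below `1e-12` are clamped with a warning.
#'
#' @param probabilities `n x K` matrix of class probabilities (rows sum
#'   to 1), or a single probability vector.
#' @param labels Integer class codes in `1..K` (or a factor).
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(probabilities, labels) {
  if (is.vector(probabilities)) probabilities <- matrix(probabilities, nrow = 1)
  labels <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  if (length(labels) != nrow(probabilities)) {
    stop("length of `labels` must match rows of `probabilities`")
  }
  p_true <- probabilities[cbind(seq_len(nrow(probabilities)), labels)]
  if (any(p_true < 1e-12)) {
    warning("true-class probabilities below 1e-12 clamped")
    p_true <- pmax(p_true, 1e-12)
  }
  mean(-log(p_true))
}

is_weight <- function(name) !grepl("_b$", name)

l2_penalty <- function(params, lambda) {
  if (lambda == 0) return(0)
  lambda * sum(vapply(names(params), function(nm) {
    if (is_weight(nm)) sum(params[[nm]]^2) else 0
  }, numeric(1)))
}

make_optimizer <- function(params, hp) {
  if (hp$optimizer == "adam") {
    list(
      m = lapply(params, function(w) array(0, dim(w) %||% length(w))),
      v = lapply(params, function(w) array(0, dim(w) %||% length(w))),
      t = 0
    )
  } else {
    list(vel = lapply(params, function(w) array(0, dim(w) %||% length(w))))
  }
}

optimizer_step <- function(params, grads, opt, hp) {
  lr <- hp$learning_rate
  if (hp$optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    opt$t <- opt$t + 1
    for (nm in names(params)) {
      g <- grads[[nm]]
      opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
      opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
      mhat <- opt$m[[nm]] / (1 - b1^opt$t)
      vhat <- opt$v[[nm]] / (1 - b2^opt$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  } else {
    for (nm in names(params)) {
      opt$vel[[nm]] <- hp$momentum * opt$vel[[nm]] - lr * grads[[nm]]
      params[[nm]] <- params[[nm]] + opt$vel[[nm]]
    }
  }
  list(params = params, opt = opt)
}

batch_loss <- function(params, config, x, y, batch = 512L) {
  n <- nrow(x)
  total <- 0
  correct <- 0
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    fw <- nn_forward(params, config, x[idx, , drop = FALSE], training = FALSE)
    p_true <- fw$probs[cbind(seq_along(idx), y[idx])]
    total <- total + sum(-log(pmax(p_true, 1e-12)))
    correct <- correct + sum(max.col(fw$probs) == y[idx])
  }
  list(loss = total / n, accuracy = correct / n)
}

#' Train a network on preprocessed feature matrices
#'
#' Runs up to `hp$epochs` epochs of seeded shuffled mini-batches, minimizing
#' cross-entropy plus `lambda * sum(weights^2)`.  Validation loss is
#' recorded each epoch; training stops early when it fails to improve for
#' `hp$patience` consecutive epochs, and the weights of the best validation
#' epoch are restored.
#'
#' @param config A [model_config()].
#' @param state0 Initial `"model_state"` (see [init_model()]).
#' @param train,validation Lists with elements `x` (matrix) and `y`
#'   (integer codes 1..K or factor), e.g. from [transform_cohort()].
#' @param hp A [hyperparams()] object.
#' @param verbose Print per-epoch losses.
#' @return An object of class `"train_state"`: best `model` weights, the
#'   per-epoch `history` data frame, `best_epoch`, `best_val_loss`,
#'   `stopped_early` and `epochs_run`.
#' @export
train_network <- function(config, state0, train, validation, hp = hyperparams(),
                          verbose = FALSE) {
  x <- as.matrix(train$x)
  y <- if (is.factor(train$y)) as.integer(train$y) else as.integer(train$y)
  xv <- as.matrix(validation$x)
  yv <- if (is.factor(validation$y)) as.integer(validation$y) else
    as.integer(validation$y)
  if (ncol(x) != ncol(xv)) stop("train and validation feature dimensions differ")
  n <- nrow(x)
  params <- unclass(state0)
  attr(params, "seed") <- NULL
  opt <- make_optimizer(params, hp)

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(params = params, val = Inf, epoch = 0L)
  stopped_early <- FALSE
  epochs_run <- 0L

  with_seed(hp$seed, {
    for (epoch in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = hp$batch_size)
      ep_loss <- 0
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + hp$batch_size - 1, n)]
        fw <- nn_forward(params, config, x[idx, , drop = FALSE], training = TRUE)
        p_true <- fw$probs[cbind(seq_along(idx), y[idx])]
        loss <- mean(-log(pmax(p_true, 1e-12)))
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch, ", batch ", bi)
        }
        ep_loss <- ep_loss + loss * length(idx)
        grads <- nn_backward(params, config, fw, y[idx])
        if (hp$l2 > 0) {
          for (nm in names(params)) {
            if (is_weight(nm)) {
              grads[[nm]] <- grads[[nm]] + 2 * hp$l2 * params[[nm]]
            }
          }
        }
        step <- optimizer_step(params, grads, opt, hp)
        params <- step$params
        opt <- step$opt
      }
      val <- batch_loss(params, config, xv, yv)
      history[epoch, ] <- list(epoch, ep_loss / n, val$loss)
      epochs_run <- epoch
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        ep_loss / n, val$loss))
      }
      if (val$loss < best$val - 1e-12) {
        best <- list(params = params, val = val$loss, epoch = epoch)
      } else if (epoch - best$epoch >= hp$patience) {
        stopped_early <- TRUE
        break
      }
    }
  })

  model <- best$params
  class(model) <- "model_state"
  attr(model, "seed") <- attr(state0, "seed")
  structure(
    list(model = model, history = history,
         best_epoch = best$epoch, best_val_loss = best$val,
         stopped_early = stopped_early, epochs_run = epochs_run,
         hp = hp, config = config),
    class = "train_state"
  )
}

#' @export
print.train_state <- function(x, ...) {
  cat("Training run:", x$epochs_run, "epoch(s)",
      if (x$stopped_early) "(stopped early)" else "", "\n")
  cat("  best validation loss", format(x$best_val_loss, digits = 5),
      "at epoch", x$best_epoch, "\n")
  invisible(x)
}
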