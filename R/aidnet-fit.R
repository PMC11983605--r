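#' Fit a hybrid convolutional-recurrent diagnostic classifier
#'
#' `aidnet()` is the package's main modelling function.  It takes a cohort
#' table, holds out a stratified validation fraction for early stopping,
#' fits the preprocessing pipeline on the training part only (imputation,
#' z-score winsorization, min-max scaling, one-hot encoding), optionally
#' balances the training classes with SMOTE, and trains the requested
#' architecture variant by backpropagation.
#'
#' @param formula Model formula, e.g. `disease ~ .`; the response must be a
#'   categorical disease label.
#' @param data Cohort `data.frame` (the training material; keep a separate
#'   test partition for evaluation).
#' @param variant Architecture variant name (see [build_variant()]) —
#'   `"full"`, `"cnn_only"`, `"cnn_lstm"`, `"cnn_topology"`, `"lstm_only"`
#'   or `"mlp_only"` — or `NULL` when `config` is supplied.
#' @param config Optional explicit [model_config()]; dimensions are filled
#'   in from the data.
#' @param hp Training [hyperparams()].
#' @param validation Optional pre-split validation cohort (same columns as
#'   `data`), e.g. the validation partition of [stratified_split()]; when
#'   supplied, all of `data` is used for training.
#' @param validation_split Fraction of `data` held out (stratified) for
#'   validation-loss monitoring when no `validation` cohort is given; the
#'   study design uses 0.1.
#' @param balance Apply SMOTE to the training partition (default `TRUE`).
#' @param smote_k SMOTE neighbour count.
#' @param impute Imputation strategy passed to [fit_preprocessor()].
#' @param seed Seed controlling the validation split, initialization, SMOTE
#'   and training stochasticity.
#' @param verbose Print per-epoch losses.
#' @param ... Further arguments passed to [build_variant()] /
#'   [model_config()] (e.g. `topology_mode`, `recurrent_cell`).
#' @return An object of class `"aidnet"` with `print()`, `summary()`,
#'   `predict()`, `coef()` and `plot()` methods.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n = 600, seed = 7, effect_size = 2))
#' fit <- aidnet(disease ~ ., cohort, variant = "mlp_only",
#'               hp = hyperparams(epochs = 15, seed = 7), seed = 7)
#' print(fit)
#' head(predict(fit, cohort, type = "prob"))
#' }
#' @export
aidnet <- function(formula = disease ~ ., data, variant = "full",
                   config = NULL, hp = hyperparams(), validation = NULL,
                   validation_split = 0.1, balance = TRUE, smote_k = 5L,
                   impute = "mean", seed = 1L, verbose = FALSE, ...) {
  cl <- match.call()
  frame_cohort <- function(d) {
    mf <- model.frame(formula, data = as.data.frame(d), na.action = NULL)
    list(response = names(mf)[1],
         cohort = cbind(mf[-1], disease = factor(mf[[1]])))
  }
  fr <- frame_cohort(data)
  response <- fr$response
  cohort <- fr$cohort

  if (is.null(validation)) {
    split <- stratified_split(cohort$disease,
                              c(1 - validation_split, validation_split),
                              seed = seed)
    train_tab <- cohort[split$train, , drop = FALSE]
    val_tab <- cohort[split$validation, , drop = FALSE]
  } else {
    train_tab <- cohort
    val_tab <- frame_cohort(validation)$cohort
    val_tab$disease <- factor(as.character(val_tab$disease),
                              levels = levels(cohort$disease))
  }

  pp <- fit_preprocessor(train_tab, impute = impute)
  fm_train <- transform_cohort(pp, train_tab)
  fm_val <- transform_cohort(pp, val_tab)

  if (balance) {
    bal <- smote(fm_train$x, factor(fm_train$y), k = smote_k, seed = seed)
    fm_train$x <- bal$x
    fm_train$y <- as.integer(bal$y)
  }

  k <- length(fm_train$class_levels)
  if (is.null(config)) {
    config <- build_variant(variant %||% "full", n_features = ncol(fm_train$x),
                            n_classes = k, dropout = hp$dropout, ...)
  } else {
    config$n_features <- ncol(fm_train$x)
    config$n_classes <- k
  }

  state0 <- init_model(config, seed = seed)
  hp$seed <- as.integer(seed)
  ts <- train_network(config, state0, fm_train, fm_val, hp, verbose = verbose)

  structure(
    list(call = cl, variant = config$variant, config = config,
         state = ts$model, preprocessor = pp,
         levels = fm_train$class_levels, response = response,
         history = ts$history, best_epoch = ts$best_epoch,
         best_val_loss = ts$best_val_loss, stopped_early = ts$stopped_early,
         epochs_run = ts$epochs_run, hp = hp, seed = as.integer(seed)),
    class = "aidnet"
  )
}

#' @export
print.aidnet <- function(x, ...) {
  cat("Hybrid diagnostic network (variant:", x$variant, ")\n")
  cat("Call: ", deparse(x$call), "\n\n")
  print(x$config)
  cat("Classes:", paste(x$levels, collapse = ", "), "\n")
  cat("Trained", x$epochs_run, "epoch(s)",
      if (x$stopped_early) "(early stopping)" else "",
      "- best validation loss", format(x$best_val_loss, digits = 4),
      "at epoch", x$best_epoch, "\n")
  invisible(x)
}

#' @export
summary.aidnet <- function(object, ...) {
  structure(
    list(fit = object, n_params = n_parameters(object$state)),
    class = "summary.aidnet"
  )
}

#' @export
print.summary.aidnet <- function(x, ...) {
  print(x$fit)
  cat("Parameters:", format(x$n_params, big.mark = ","), "\n")
  h <- x$fit$history
  if (nrow(h)) {
    cat("Final train loss:", format(h$train_loss[nrow(h)], digits = 4),
        "| final validation loss:", format(h$val_loss[nrow(h)], digits = 4), "\n")
  }
  invisible(x)
}

#' Predict disease classes or probabilities
#'
#' @param object A fitted `"aidnet"` model.
#' @param newdata Cohort `data.frame` with the predictor columns.
#' @param type `"class"` (default) for hard labels, `"prob"` for the class
#'   probability matrix.
#' @param ... Unused.
#' @return A factor of predicted labels, or an `n x K` probability matrix.
#' @export
predict.aidnet <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  fm <- transform_cohort(object$preprocessor, as.data.frame(newdata))
  probs <- predict_matrix(object, fm$x)
  if (type == "prob") return(probs)
  factor(object$levels[max.col(probs)], levels = object$levels)
}

# probability predictions straight from a preprocessed matrix
predict_matrix <- function(object, x, batch = 1024L) {
  n <- nrow(x)
  out <- matrix(0, n, length(object$levels),
                dimnames = list(NULL, object$levels))
  for (start in seq(1, max(n, 1), by = batch)) {
    if (n == 0) break
    idx <- start:min(start + batch - 1, n)
    fw <- nn_forward(unclass(object$state), object$config,
                     x[idx, , drop = FALSE], training = FALSE)
    out[idx, ] <- fw$probs
  }
  out
}

#' @export
coef.aidnet <- function(object, ...) {
  object$state
}

#' Plot training and validation loss curves
#' @param x A fitted `"aidnet"` model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.aidnet <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l", lty = 1,
          col = c("steelblue", "firebrick"), xlab = "epoch",
          ylab = "cross-entropy loss", ...)
  abline(v = x$best_epoch, lty = 3, col = "grey40")
  legend("topright", c("train", "validation"), lty = 1,
         col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Evaluate a fitted model on a held-out cohort
#'
#' @param object A fitted `"aidnet"` model (or any object with a
#'   `predict()` method returning classes and probabilities).
#' @param newdata Held-out cohort `data.frame` including the disease label.
#' @return A [metrics_report()] with confusion matrix, accuracy, macro
#'   precision/recall/F1 and one-vs-rest AUC-ROC / AUC-PR.
#' @export
evaluate_model <- function(object, newdata) {
  newdata <- as.data.frame(newdata)
  y_true <- factor(as.character(newdata[[object$response %||% "disease"]]),
                   levels = object$levels)
  probs <- predict(object, newdata, type = "prob")
  y_pred <- factor(object$levels[max.col(probs)], levels = object$levels)
  metrics_report(y_true, y_pred, scores = probs)
}
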