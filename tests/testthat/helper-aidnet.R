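# Shared fixtures: all built in code at test time.

# small complete cohort with learnable signal
small_cohort <- function(n = 400, seed = 1, effect_size = 2,
                         missing_rate = 0, ...) {
  generate_cohort(cohort_spec(n = n, seed = seed, effect_size = effect_size,
                              missing_rate = missing_rate, ...))
}

# tiny model configuration that keeps gradient checks and training fast
tiny_config <- function(...) {
  model_config(n_features = 7, n_classes = 3, conv_channels = c(2L, 3L),
               hidden_size = 4L, seq_len = 2L, feature_dim = 3L,
               dropout = 0, ...)
}

# central-difference gradient check over every parameter tensor; returns the
# worst absolute deviation between analytic and numeric gradients
max_gradient_error <- function(config, seed = 3, n = 6, eps = 1e-6,
                               max_per_tensor = 60L) {
  params <- unclass(init_model(config, seed = seed))
  x <- with_seed_test(seed + 1, matrix(runif(n * config$n_features), n))
  y <- with_seed_test(seed + 2, sample(seq_len(config$n_classes), n, replace = TRUE))
  fw <- aidnet:::nn_forward(params, config, x)
  grads <- aidnet:::nn_backward(params, config, fw, y)
  loss_fn <- function(p) cross_entropy(aidnet:::nn_forward(p, config, x)$probs, y)
  worst <- 0
  for (nm in names(params)) {
    for (i in seq_len(min(length(params[[nm]]), max_per_tensor))) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      worst <- max(worst, abs(num - grads[[nm]][i]))
    }
  }
  worst
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# brute-force metric oracles, deliberately naive
oracle_prf <- function(y_true, y_pred, k) {
  prec <- rec <- f1 <- numeric(k)
  for (cl in seq_len(k)) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec[cl] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[cl] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[cl] <- if (prec[cl] + rec[cl] == 0) 0 else
      2 * prec[cl] * rec[cl] / (prec[cl] + rec[cl])
  }
  list(precision = 100 * mean(prec), recall = 100 * mean(rec),
       f1 = 100 * mean(f1), accuracy = 100 * mean(y_true == y_pred))
}

# AUC-ROC by exhaustive pair enumeration (+1 concordant, +0.5 tie)
oracle_auc_binary <- function(scores, positive) {
  pos <- which(positive); neg <- which(!positive)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# AUC-PR by exhaustive threshold enumeration: sum of dRecall x precision
oracle_ap_binary <- function(scores, positive) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(positive)
  prev_rec <- 0
  area <- 0
  for (t in ths) {
    sel <- scores >= t
    prec <- sum(positive & sel) / sum(sel)
    rec <- sum(positive & sel) / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}
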