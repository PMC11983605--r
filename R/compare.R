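# Multi-run model comparison: per-model mean accuracy with t-based 95%
# confidence intervals and two-sided paired t-tests against a reference
# model, plus adapters wrapping the standard baseline learners behind a
# uniform fit/predict surface.

#' Compare models over paired runs
#'
#' Computes, per model, the mean metric over `R` paired runs with a
#' t-based `1 - alpha` confidence-interval half-width, and a two-sided
#' paired t-test of the reference model against each competitor.  When the
#' run-wise differences have zero variance, the p-value is reported as 1
#' for a zero mean difference and flagged as degenerate (p -> 0) for a
#' nonzero one.
#'
#' @param results `R x M` numeric matrix (runs x models) of a paired metric
#'   (e.g. accuracy in percent), with model names as column names, or a
#'   data frame of the same shape.
#' @param reference Column name of the reference model.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `"comparison_report"`: data frame with mean,
#'   CI half-width, p-value vs the reference and a significance flag.
#' @export
multi_run_compare <- function(results, reference, alpha = 0.05) {
  results <- as.matrix(results)
  if (is.null(colnames(results))) stop("`results` needs model column names")
  if (!reference %in% colnames(results)) {
    stop("reference model `", reference, "` not among columns")
  }
  if (anyNA(results)) stop("all models need the same number of paired runs")
  r <- nrow(results)
  if (r < 2) stop("need at least 2 runs")
  tcrit <- qt(1 - alpha / 2, df = r - 1)
  out <- data.frame(
    model = colnames(results),
    mean = colMeans(results),
    ci_half_width = tcrit * apply(results, 2, sd) / sqrt(r),
    p_value = NA_real_,
    significant = NA,
    row.names = NULL
  )
  for (m in colnames(results)) {
    if (m == reference) next
    d <- results[, reference] - results[, m]
    i <- which(out$model == m)
    if (sd(d) < 1e-12) {
      out$p_value[i] <- if (abs(mean(d)) < 1e-12) 1 else 0
    } else {
      out$p_value[i] <- t.test(results[, reference], results[, m],
                               paired = TRUE)$p.value
    }
    out$significant[i] <- out$p_value[i] < alpha
  }
  structure(list(table = out, reference = reference, alpha = alpha, runs = r),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Model comparison over", x$runs, "paired runs (reference:",
      x$reference, ")\n\n")
  tab <- x$table
  tab$mean <- round(tab$mean, 1)
  tab$ci_half_width <- round(tab$ci_half_width, 2)
  tab$p_value <- ifelse(is.na(tab$p_value), "- (reference)",
                        format.pval(tab$p_value, digits = 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

AID_BASELINES <- c("svm", "rf", "knn", "lr")

#' Fit a standard baseline classifier
#'
#' Uniform adapter over the comparator learners: `"svm"` (radial SVM,
#' \pkg{e1071}), `"rf"` (random forest, \pkg{randomForest}), `"knn"`
#' (k-nearest neighbours, \pkg{class}), `"lr"` (multinomial logistic
#' regression, \pkg{nnet}).  These are comparators, not contributions, and
#' are delegated to their reference implementations.
#'
#' @param name Baseline name.
#' @param x Numeric training feature matrix.
#' @param y Training labels (factor).
#' @param seed RNG seed for stochastic learners.
#' @param knn_k Neighbour count for `"knn"`.
#' @return An object of class `"aid_baseline"` with a `predict()` method
#'   returning a list with `class` (factor) and `prob` (matrix or `NULL`).
#' @export
fit_baseline <- function(name, x, y, seed = 1L, knn_k = 5L) {
  name <- match.arg(name, AID_BASELINES)
  y <- droplevels(as.factor(y))
  x <- as.matrix(x)
  fit <- with_seed(seed, switch(name,
    svm = {
      requireNamespace("e1071")
      e1071::svm(x, y, probability = TRUE)
    },
    rf = {
      requireNamespace("randomForest")
      randomForest::randomForest(x, y)
    },
    knn = list(x = x, y = y, k = as.integer(knn_k)),
    lr = {
      requireNamespace("nnet")
      df <- data.frame(.y = y, x)
      nnet::multinom(.y ~ ., df, trace = FALSE,
                     MaxNWts = (ncol(x) + 2) * nlevels(y) + 1)
    }
  ))
  structure(list(name = name, fit = fit, levels = levels(y)),
            class = "aid_baseline")
}

#' @export
predict.aid_baseline <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  lv <- object$levels
  out <- switch(object$name,
    svm = {
      cls <- predict(object$fit, x, probability = TRUE)
      pr <- attr(cls, "probabilities")
      list(class = factor(as.character(cls), levels = lv),
           prob = pr[, lv, drop = FALSE])
    },
    rf = {
      pr <- predict(object$fit, x, type = "prob")
      list(class = factor(lv[max.col(pr[, lv, drop = FALSE])], levels = lv),
           prob = pr[, lv, drop = FALSE])
    },
    knn = {
      requireNamespace("class")
      cls <- class::knn(object$fit$x, x, object$fit$y, k = object$fit$k)
      list(class = factor(as.character(cls), levels = lv), prob = NULL)
    },
    lr = {
      pr <- predict(object$fit, data.frame(x), type = "probs")
      if (is.null(dim(pr))) pr <- cbind(1 - pr, pr, deparse.level = 0)
      colnames(pr) <- lv
      list(class = factor(lv[max.col(pr)], levels = lv), prob = pr)
    }
  )
  out
}

#' Run the multi-model comparison harness
#'
#' For each of `runs` seeded repetitions: draws a stratified 80/10/10
#' split of the cohort, fits the preprocessing pipeline on the training
#' partition, balances it with SMOTE, trains every requested model on the
#' identical material, and records test accuracy (percent).  The paired
#' accuracies then go through [multi_run_compare()].
#'
#' @param cohort Cohort `data.frame` with a `disease` column.
#' @param models Character vector mixing baseline names (`"svm"`, `"rf"`,
#'   `"knn"`, `"lr"`) and architecture variants (`"full"`, `"mlp_only"`,
#'   ...).
#' @param reference Reference model for the paired tests (default
#'   `"full"`).
#' @param runs Number of independent runs (the study design uses 5).
#' @param hp Training hyperparameters for the network variants.
#' @param seed Base seed; run `r` uses `seed + r`.
#' @return A `"comparison_report"`; the per-run accuracy matrix is attached
#'   as attribute `"runs_matrix"`.
#' @export
compare_models <- function(cohort, models = c("full", AID_BASELINES),
                           reference = "full", runs = 5L,
                           hp = hyperparams(), seed = 1L) {
  acc <- matrix(NA_real_, runs, length(models),
                dimnames = list(NULL, models))
  for (r in seq_len(runs)) {
    run_seed <- seed + r
    split <- stratified_split(cohort$disease, seed = run_seed)
    train_tab <- cohort[split$train, , drop = FALSE]
    test_tab <- cohort[split$test, , drop = FALSE]
    pp <- fit_preprocessor(train_tab)
    fm_tr <- transform_cohort(pp, train_tab)
    fm_te <- transform_cohort(pp, test_tab)
    bal <- smote(fm_tr$x, factor(fm_tr$y), seed = run_seed)
    y_tr <- factor(fm_tr$class_levels[as.integer(bal$y)],
                   levels = fm_tr$class_levels)
    y_te <- factor(fm_te$class_levels[fm_te$y], levels = fm_te$class_levels)

    for (m in models) {
      if (m %in% AID_BASELINES) {
        b <- fit_baseline(m, bal$x, y_tr, seed = run_seed)
        pred <- predict(b, fm_te$x)$class
      } else {
        fit <- aidnet(disease ~ ., train_tab, variant = m, hp = hp,
                      seed = run_seed,
                      validation = cohort[split$validation, , drop = FALSE])
        pred <- predict(fit, test_tab)
      }
      acc[r, m] <- 100 * mean(pred == y_te)
    }
  }
  rep <- multi_run_compare(acc, reference = reference)
  attr(rep, "runs_matrix") <- acc
  rep
}
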