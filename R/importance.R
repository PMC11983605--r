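# Model-agnostic permutation feature importance: the drop in held-out
# accuracy when one predictor column is shuffled.  One-hot blocks derived
# from a single categorical predictor are permuted jointly by shuffling the
# raw column before transformation, so the report has one row per clinical
# predictor.

#' Permutation feature importance
#'
#' Importance of a predictor is the baseline accuracy minus the mean
#' accuracy over `n_repeats` seeded shuffles of that predictor's raw column
#' (the preprocessing transform is re-applied after each shuffle, so one-hot
#' blocks move together).  Features the model provably ignores score
#' exactly 0.
#'
#' @param object A fitted `"aidnet"` model (anything with a compatible
#'   `predict(object, newdata)` returning a factor works via the `predict_fn`
#'   hook).
#' @param newdata Labelled evaluation cohort (>= 2 rows).
#' @param n_repeats Number of shuffles per feature.
#' @param seed RNG seed.
#' @param predict_fn Optional `function(object, newdata)` returning
#'   predicted labels; defaults to `predict()` for hard classes.
#' @return An object of class `"attribution_report"`: data frame with
#'   `feature`, `importance` (accuracy-drop on the percent scale), and
#'   `sd` across repeats, sorted by descending importance.
#' @export
permutation_importance <- function(object, newdata, n_repeats = 5L, seed = 1L,
                                   predict_fn = NULL) {
  newdata <- as.data.frame(newdata)
  if (nrow(newdata) < 2) stop("need at least 2 evaluation rows")
  response <- if (inherits(object, "aidnet")) object$response else "disease"
  if (!response %in% names(newdata)) stop("`newdata` lacks the label column")
  y <- as.character(newdata[[response]])
  if (is.null(predict_fn)) {
    predict_fn <- function(obj, nd) as.character(predict(obj, nd))
  }
  features <- setdiff(names(newdata), c(response, "patient_id", "visit"))
  baseline <- 100 * mean(predict_fn(object, newdata) == y)

  imp <- matrix(NA_real_, length(features), n_repeats,
                dimnames = list(features, NULL))
  with_seed(seed, {
    for (f in features) {
      for (r in seq_len(n_repeats)) {
        shuffled <- newdata
        shuffled[[f]] <- shuffled[[f]][sample.int(nrow(newdata))]
        acc <- 100 * mean(predict_fn(object, shuffled) == y)
        imp[f, r] <- baseline - acc
      }
    }
  })
  tab <- data.frame(
    feature = features,
    importance = rowMeans(imp),
    sd = apply(imp, 1, sd),
    row.names = NULL
  )
  tab <- tab[order(-tab$importance), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, baseline_accuracy = baseline,
                 n_repeats = n_repeats, seed = seed),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("Permutation importance (baseline accuracy ",
      round(x$baseline_accuracy, 1), "%, ", x$n_repeats, " repeats)\n\n",
      sep = "")
  tab <- x$table
  tab$importance <- round(tab$importance, 2)
  tab$sd <- round(tab$sd, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
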