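# Ablation harness: trains and evaluates the six architecture variants on
# identical splits and hyperparameters across seeds, reporting mean
# accuracy, macro precision/recall/F1 and AUC-ROC per variant.

#' Run the six-variant ablation study
#'
#' For each seed: draws a stratified 80/10/10 split shared by every
#' variant, then trains and evaluates each of the six architecture variants
#' (full, cnn_only, cnn_lstm, cnn_topology, lstm_only, mlp_only) with
#' identical hyperparameters.  Reports per-variant means over seeds.  A
#' variant that fails to train is recorded with `NA` metrics and the error
#' message, and the remaining variants still run.
#'
#' @param cohort Cohort `data.frame` with a `disease` column.
#' @param hp Shared training [hyperparams()].
#' @param seeds Integer vector of run seeds.
#' @param variants Variant names (default all six).
#' @return An object of class `"ablation_report"`: data frame of mean
#'   metrics per variant plus a `runs` array of per-seed metrics.
#' @export
run_ablation <- function(cohort, hp = hyperparams(), seeds = 1:5,
                         variants = AID_VARIANTS) {
  stopifnot(all(variants %in% AID_VARIANTS))
  metrics <- c("accuracy", "precision", "recall", "f1", "auc_roc")
  runs <- array(NA_real_, c(length(variants), length(seeds), length(metrics)),
                dimnames = list(variants, paste0("seed", seeds), metrics))
  failures <- list()

  for (si in seq_along(seeds)) {
    s <- seeds[si]
    split <- stratified_split(cohort$disease, seed = s)
    train_tab <- cohort[split$train, , drop = FALSE]
    val_tab <- cohort[split$validation, , drop = FALSE]
    test_tab <- cohort[split$test, , drop = FALSE]
    for (v in variants) {
      res <- tryCatch({
        fit <- aidnet(disease ~ ., train_tab, variant = v, hp = hp, seed = s,
                      validation = val_tab)
        rep <- evaluate_model(fit, test_tab)
        c(rep$accuracy, rep$precision, rep$recall, rep$f1, rep$auc_roc)
      }, error = function(e) {
        failures[[paste(v, s, sep = "/")]] <<- conditionMessage(e)
        rep(NA_real_, length(metrics))
      })
      runs[v, si, ] <- res
    }
  }

  means <- apply(runs, c(1, 3), mean)
  tab <- data.frame(variant = variants, means, row.names = NULL)
  structure(list(table = tab, runs = runs, seeds = seeds, hp = hp,
                 failures = failures),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("Ablation study over", length(x$seeds), "seed(s)\n\n")
  tab <- x$table
  for (col in c("accuracy", "precision", "recall", "f1")) {
    tab[[col]] <- round(tab[[col]], 1)
  }
  tab$auc_roc <- round(tab$auc_roc, 2)
  print(tab, row.names = FALSE)
  if (length(x$failures)) {
    cat("\nFailed runs:\n")
    for (nm in names(x$failures)) cat(" ", nm, ":", x$failures[[nm]], "\n")
  }
  invisible(x)
}

#' Serialize a report as JSON
#'
#' Works for metrics, comparison, ablation and attribution reports.
#'
#' @param report A report object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  obj <- unclass(report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
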