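# Leakage-free preprocessing pipeline: train-fitted imputation, z-score
# winsorization, min-max scaling, one-hot encoding, stratified splitting and
# SMOTE oversampling.  All statistics live in the fitted preprocessor state;
# transforming validation/test data never touches their own statistics.

#' Fit a preprocessor on training data
#'
#' Computes, from the training partition only: per-feature imputation values
#' (mean for continuous, mode for categorical, or a k-NN strategy), post-
#' imputation mean/SD for z-score winsorization, min-max bounds on the
#' winsorized training values, and deterministic (lexicographic) category
#' levels.
#'
#' @param train Training cohort `data.frame` (must contain a `disease`
#'   column or be all-predictor).
#' @param impute Imputation strategy for continuous features: `"mean"`
#'   (default), `"median"`, or `"knn"`.  Categorical features always use the
#'   mode.
#' @param knn_k Neighbour count for `impute = "knn"`.
#' @param outlier_threshold Absolute z-score beyond which continuous values
#'   are winsorized to mean +/- threshold * SD; `Inf` disables.
#' @return An object of class `"aid_preprocessor"`.
#' @seealso [transform_cohort()], [inverse_transform()]
#' @export
fit_preprocessor <- function(train, impute = c("mean", "median", "knn"),
                             knn_k = 5L, outlier_threshold = 3) {
  impute <- match.arg(impute)
  train <- as.data.frame(train)
  if (nrow(train) == 0) stop("training data is empty")
  predictors <- setdiff(names(train), c("disease", "patient_id", "visit"))
  is_cat <- vapply(train[predictors], function(v) is.character(v) || is.factor(v),
                   logical(1))
  continuous <- predictors[!is_cat]
  categorical <- predictors[is_cat]

  for (f in predictors) {
    if (all(is.na(train[[f]]))) {
      stop("feature `", f, "` has no non-missing training values; cannot fit")
    }
  }

  impute_values <- list()
  for (f in continuous) {
    v <- train[[f]]
    impute_values[[f]] <- switch(impute,
      mean = mean(v, na.rm = TRUE),
      median = stats::median(v, na.rm = TRUE),
      knn = mean(v, na.rm = TRUE)  # fallback value when no complete donor exists
    )
  }
  for (f in categorical) {
    v <- as.character(train[[f]])
    tb <- sort(table(v[!is.na(v)]), decreasing = TRUE)
    impute_values[[f]] <- names(tb)[1]
  }

  levels_list <- lapply(train[categorical], function(v) {
    sort(unique(as.character(v[!is.na(v)])))
  })

  state <- structure(
    list(impute = impute, knn_k = as.integer(knn_k),
         impute_values = impute_values,
         outlier_threshold = outlier_threshold,
         continuous = continuous, categorical = categorical,
         levels = levels_list),
    class = "aid_preprocessor"
  )

  imputed <- impute_table(state, train, donors = train)
  center <- vapply(imputed[continuous], mean, numeric(1))
  spread <- vapply(imputed[continuous], sd, numeric(1))
  spread[is.na(spread)] <- 0
  state$center <- center
  state$spread <- spread

  wins <- imputed
  for (f in continuous) {
    wins[[f]] <- winsorize(wins[[f]], center[f], spread[f], outlier_threshold)
  }
  state$min <- vapply(wins[continuous], min, numeric(1))
  state$max <- vapply(wins[continuous], max, numeric(1))

  if (impute == "knn") {
    # donor pool: complete training rows, min-max scaled for distances
    comp <- imputed[complete.cases(train[predictors]), , drop = FALSE]
    if (nrow(comp) == 0) {
      warning("no complete training rows; k-NN imputation falls back to the mean")
    }
    state$knn_donors <- comp
    state$knn_scaled <- scale_continuous(state, comp)
  }
  state
}

#' @export
print.aid_preprocessor <- function(x, ...) {
  cat("Fitted preprocessor (", x$impute, " imputation, |z| > ",
      x$outlier_threshold, " winsorized)\n", sep = "")
  cat("  continuous: ", length(x$continuous), " features scaled to [0, 1]\n", sep = "")
  cat("  categorical:", length(x$categorical), "features one-hot encoded\n")
  invisible(x)
}

winsorize <- function(v, center, spread, threshold) {
  if (spread == 0 || !is.finite(threshold)) return(v)
  pmin(pmax(v, center - threshold * spread), center + threshold * spread)
}

scale_continuous <- function(state, table) {
  out <- matrix(0, nrow(table), length(state$continuous),
                dimnames = list(NULL, state$continuous))
  for (f in state$continuous) {
    rng <- state$max[f] - state$min[f]
    out[, f] <- if (rng == 0) 0 else (table[[f]] - state$min[f]) / rng
  }
  out
}

impute_table <- function(state, table, donors = NULL) {
  out <- as.data.frame(table)
  if (state$impute == "knn" && !is.null(state$knn_donors) &&
      nrow(state$knn_donors) > 0) {
    out <- impute_knn(state, out)
  }
  for (f in c(state$continuous, state$categorical)) {
    miss <- is.na(out[[f]])
    if (any(miss)) out[[f]][miss] <- state$impute_values[[f]]
  }
  for (f in state$categorical) out[[f]] <- as.character(out[[f]])
  out
}

# k-NN imputation: for each incomplete row, distance to complete training
# donors over the continuous features observed in that row (min-max scaled);
# missing continuous cells take the mean of the k nearest donors, missing
# categorical cells their mode.
impute_knn <- function(state, table) {
  donors <- state$knn_donors
  dscaled <- state$knn_scaled
  k <- max(1L, state$knn_k)
  rows <- which(!complete.cases(table[c(state$continuous, state$categorical)]))
  if (!length(rows)) return(table)
  tscaled <- scale_continuous(state, impute_table_meanonly(state, table))
  for (r in rows) {
    obs <- state$continuous[!is.na(table[r, state$continuous])]
    d <- if (length(obs)) {
      sqrt(colSums((t(dscaled[, obs, drop = FALSE]) - tscaled[r, obs])^2))
    } else {
      rep(0, nrow(donors))
    }
    nn <- order(d)[seq_len(min(k, nrow(donors)))]
    for (f in state$continuous) {
      if (is.na(table[r, f])) table[r, f] <- mean(donors[nn, f])
    }
    for (f in state$categorical) {
      if (is.na(table[r, f])) {
        tb <- sort(base::table(as.character(donors[nn, f])), decreasing = TRUE)
        table[r, f] <- names(tb)[1]
      }
    }
  }
  table
}

impute_table_meanonly <- function(state, table) {
  out <- as.data.frame(table)
  for (f in state$continuous) {
    miss <- is.na(out[[f]])
    if (any(miss)) out[[f]][miss] <- state$impute_values[[f]]
  }
  out
}

#' Transform a cohort into a numeric feature matrix
#'
#' Applies a fitted preprocessor: imputation, z-score winsorization (train
#' statistics), min-max scaling with clipping to `[0, 1]`, and one-hot
#' expansion of categoricals.  Unseen categories map to an all-zero block
#' with a warning.
#'
#' @param state A fitted [fit_preprocessor()] object.
#' @param table Cohort `data.frame` conforming to the training schema.
#' @return A list of class `"feature_matrix"` with elements `x` (numeric
#'   matrix), `y` (integer class codes, or `NULL` when `disease` is absent),
#'   `class_levels`, and `groups` (source predictor of each column).
#' @export
transform_cohort <- function(state, table) {
  if (!inherits(state, "aid_preprocessor")) stop("`state` must be a fitted preprocessor")
  table <- as.data.frame(table)
  missing_cols <- setdiff(c(state$continuous, state$categorical), names(table))
  if (length(missing_cols)) {
    stop("table lacks feature(s): ", paste(missing_cols, collapse = ", "))
  }
  imp <- impute_table(state, table)
  n <- nrow(imp)

  cont <- matrix(0, n, length(state$continuous),
                 dimnames = list(NULL, state$continuous))
  for (f in state$continuous) {
    v <- winsorize(imp[[f]], state$center[f], state$spread[f],
                   state$outlier_threshold)
    rng <- state$max[f] - state$min[f]
    # constant training feature maps to 0; out-of-range values are clipped
    cont[, f] <- if (rng == 0) 0 else pmin(1, pmax(0, (v - state$min[f]) / rng))
  }

  blocks <- list(cont)
  groups <- state$continuous
  for (f in state$categorical) {
    lev <- state$levels[[f]]
    v <- as.character(imp[[f]])
    unseen <- !(v %in% lev)
    if (any(unseen)) {
      warning("feature `", f, "`: ", sum(unseen),
              " value(s) outside training categories mapped to a zero block")
    }
    oh <- matrix(0, n, length(lev), dimnames = list(NULL, paste(f, lev, sep = ".")))
    for (j in seq_along(lev)) oh[, j] <- as.numeric(v == lev[j])
    blocks[[length(blocks) + 1]] <- oh
    groups <- c(groups, rep(f, length(lev)))
  }
  x <- do.call(cbind, blocks)

  y <- NULL
  class_levels <- NULL
  if ("disease" %in% names(table)) {
    d <- table$disease
    class_levels <- if (is.factor(d)) levels(d) else sort(unique(as.character(d)))
    y <- as.integer(factor(as.character(d), levels = class_levels))
  }
  structure(list(x = x, y = y, class_levels = class_levels, groups = groups),
            class = "feature_matrix")
}

#' @rdname transform_cohort
#' @param object,newdata,... `predict()` interface: `object` is the fitted
#'   preprocessor, `newdata` the cohort to transform.
#' @export
predict.aid_preprocessor <- function(object, newdata, ...) {
  transform_cohort(object, newdata)
}

#' Invert the min-max scaling of continuous features
#'
#' Maps scaled values in `[0, 1]` back to the original units via
#' `x * (max - min) + min`.  Exact for in-range, non-winsorized values.
#'
#' @param state A fitted preprocessor.
#' @param x Numeric matrix whose columns include the continuous features.
#' @return Matrix with continuous columns back on their original scales.
#' @export
inverse_transform <- function(state, x) {
  out <- x
  for (f in intersect(colnames(x), state$continuous)) {
    out[, f] <- x[, f] * (state$max[f] - state$min[f]) + state$min[f]
  }
  out
}

#' Flag and winsorize outliers by z-score
#'
#' Flags entries with `|x - mean| / sd > threshold` and clamps them to
#' `mean +/- threshold * sd`.  A zero-variance vector yields an empty mask
#' and is returned unchanged.
#'
#' @param values Numeric vector (`NA`s are ignored and never flagged).
#' @param threshold Positive z-score cutoff (default 3).
#' @return A list with `mask` (logical) and `values` (winsorized vector).
#' @export
zscore_outliers <- function(values, threshold = 3) {
  m <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0 || !is.finite(threshold)) {
    return(list(mask = rep(FALSE, length(values)), values = values))
  }
  z <- (values - m) / s
  mask <- !is.na(z) & abs(z) > threshold
  out <- values
  out[mask] <- pmin(pmax(values[mask], m - threshold * s), m + threshold * s)
  list(mask = mask, values = out)
}

#' Stratified train/validation/test split
#'
#' Allocates each class across the partitions by largest-remainder rounding
#' (ties resolved toward the earlier partition and lower class index), then
#' reconciles against the largest-remainder global partition sizes, so both
#' the per-class proportions (within one record of exact) and the overall
#' fractions are honoured.  Shuffling within class is seeded.
#'
#' @param labels Class label vector (factor or character).
#' @param fractions Positive partition fractions summing to 1; default the
#'   study design `c(0.8, 0.1, 0.1)`.
#' @param seed RNG seed for the within-class shuffle.
#' @return An object of class `"split_indices"`: list with integer index
#'   vectors `train`, `validation`, `test`.
#' @export
stratified_split <- function(labels, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (any(fractions <= 0)) stop("`fractions` must be positive")
  if (abs(sum(fractions) - 1) > 1e-8) stop("`fractions` must sum to 1")
  labels <- as.factor(labels)
  classes <- levels(labels)[tabulate(labels, length(levels(labels))) > 0]
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  P <- length(fractions)
  K <- length(classes)

  quota <- outer(as.numeric(counts), fractions)
  alloc <- floor(quota + 1e-9)
  rem <- quota - alloc

  gq <- sum(counts) * fractions
  target <- floor(gq + 1e-9)
  short <- sum(counts) - sum(target)
  if (short > 0) {
    ord <- order(gq - target, decreasing = TRUE)[seq_len(short)]
    target[ord] <- target[ord] + 1
  }
  cap <- target - colSums(alloc)
  give <- counts - rowSums(alloc)

  for (idx in order(as.vector(rem), decreasing = TRUE)) {
    k <- (idx - 1) %% K + 1
    p <- (idx - 1) %/% K + 1
    if (give[k] > 0 && cap[p] > 0) {
      alloc[k, p] <- alloc[k, p] + 1
      give[k] <- give[k] - 1
      cap[p] <- cap[p] - 1
    }
  }
  while (sum(give) > 0) {  # capacity-only fallback; unreachable in typical data
    k <- which(give > 0)[1]
    p <- which(cap > 0)[1]
    alloc[k, p] <- alloc[k, p] + 1
    give[k] <- give[k] - 1
    cap[p] <- cap[p] - 1
  }

  parts <- vector("list", P)
  with_seed(seed, {
    for (k in seq_len(K)) {
      idx <- which(labels == classes[k])
      idx <- idx[sample.int(length(idx))]
      at <- 0
      for (p in seq_len(P)) {
        take <- alloc[k, p]
        parts[[p]] <- c(parts[[p]], idx[seq_len(take) + at])
        at <- at + take
      }
    }
  })
  parts <- lapply(parts, sort)
  structure(
    list(train = parts[[1]],
         validation = if (P >= 2) parts[[2]] else integer(0),
         test = if (P >= 3) parts[[3]] else integer(0),
         fractions = fractions, seed = seed),
    class = "split_indices"
  )
}

#' @export
print.split_indices <- function(x, ...) {
  cat("Stratified split:", length(x$train), "train /",
      length(x$validation), "validation /", length(x$test), "test\n")
  invisible(x)
}

#' SMOTE oversampling of minority classes
#'
#' Oversamples every minority class up to the majority-class count.  Each
#' synthetic row is `x + lambda * (x_nn - x)` with `lambda ~ U(0, 1)`, `x` a
#' minority row and `x_nn` one of its `k` nearest same-class neighbours
#' under Euclidean distance.  Majority rows are never altered; intended for
#' the training partition only.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Class labels aligned with `x`.
#' @param k Neighbour count (default 5; capped at class size - 1).
#' @param seed RNG seed.
#' @return A list with oversampled `x` and `y` (original rows first).
#' @export
smote <- function(x, y, k = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (k < 1) stop("`k` must be >= 1")
  counts <- table(y)
  counts <- counts[counts > 0]
  n_max <- max(counts)
  if (all(counts == n_max)) return(list(x = x, y = y))

  new_x <- list()
  new_y <- list()
  with_seed(seed, {
    for (cl in names(counts)) {
      n_c <- counts[[cl]]
      need <- n_max - n_c
      if (need == 0) next
      if (n_c < 2) {
        stop("class `", cl, "` has a single member; lower `k` or merge classes")
      }
      rows <- which(y == cl)
      xc <- x[rows, , drop = FALSE]
      k_eff <- min(k, n_c - 1)
      d <- as.matrix(stats::dist(xc))
      diag(d) <- Inf
      nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_eff)]))
      if (k_eff == 1) nn <- matrix(nn, ncol = 1)

      base <- sample.int(n_c, need, replace = TRUE)
      pick <- nn[cbind(base, sample.int(k_eff, need, replace = TRUE))]
      lambda <- runif(need)
      synth <- xc[base, , drop = FALSE] +
        lambda * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
      new_x[[cl]] <- synth
      new_y[[cl]] <- rep(cl, need)
    }
  })
  list(
    x = rbind(x, do.call(rbind, new_x)),
    y = factor(c(as.character(y), unlist(new_y, use.names = FALSE)),
               levels = levels(y))
  )
}

#' Serialize a fitted preprocessor to JSON (and back)
#'
#' The JSON sidecar holds imputation values, winsorization statistics,
#' min-max bounds and category levels for exact reuse.
#'
#' @param state A fitted preprocessor.
#' @param path File path for the JSON sidecar.
#' @return `preprocessor_to_json()` returns `path`; `preprocessor_from_json()`
#'   returns the restored `"aid_preprocessor"`.
#' @export
preprocessor_to_json <- function(state, path) {
  keep <- state[setdiff(names(state), c("knn_donors", "knn_scaled"))]
  for (f in c("center", "spread", "min", "max")) {
    keep[[f]] <- as.list(keep[[f]])  # named lists keep their names in JSON
  }
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname preprocessor_to_json
#' @export
preprocessor_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("center", "spread", "min", "max")) {
    raw[[f]] <- unlist(raw[[f]])
  }
  raw$impute_values <- as.list(raw$impute_values)
  raw$levels <- as.list(raw$levels)
  structure(raw, class = "aid_preprocessor")
}
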