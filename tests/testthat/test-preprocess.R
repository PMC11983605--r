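# Preprocessing pipeline: imputation, scaling, outliers, splitting, SMOTE.

make_train <- function() {
  data.frame(
    cholesterol = c(180, 200, NA, 160),
    bmi = c(22, NA, 30, 26),
    family_history = c("yes", "yes", "no", NA),
    disease = factor(c("RA", "SLE", "RA", "SLE")),
    stringsAsFactors = FALSE
  )
}

test_that("mean and mode imputation values come from the training data", {
  pp <- fit_preprocessor(make_train())
  expect_equal(pp$impute_values$cholesterol, mean(c(180, 200, 160)))
  expect_equal(pp$impute_values$family_history, "yes")

  two <- data.frame(cholesterol = c(180, 200, NA), disease = factor(c("a", "b", "a")))
  pp2 <- fit_preprocessor(two)
  expect_equal(pp2$impute_values$cholesterol, 190)
})

test_that("fitting fails loudly on an entirely missing feature", {
  bad <- data.frame(x = c(NA_real_, NA_real_), disease = factor(c("a", "b")))
  expect_error(fit_preprocessor(bad), "x")
})

test_that("k-NN imputation with k = 1 copies the nearest complete row", {
  train <- data.frame(
    a = c(0, 1, 10, NA),
    b = c(0, 1, 10, 1.1),
    disease = factor(rep(c("x", "y"), 2))
  )
  pp <- fit_preprocessor(train, impute = "knn", knn_k = 1)
  out <- aidnet:::impute_table(pp, train)
  # row 4 observes only b = 1.1; nearest complete row by scaled distance is row 2
  complete <- train[1:3, ]
  scaled_b <- (complete$b - pp$min["b"]) / (pp$max["b"] - pp$min["b"])
  target <- (1.1 - pp$min["b"]) / (pp$max["b"] - pp$min["b"])
  nearest <- which.min(abs(scaled_b - target))
  expect_equal(out$a[4], complete$a[nearest])
})

test_that("min-max transform maps midpoints, degenerate and unseen values correctly", {
  train <- data.frame(x = c(100, 200), cst = c(5, 5),
                      g = c("a", "b"), disease = factor(c("u", "v")))
  pp <- fit_preprocessor(train, outlier_threshold = Inf)
  fm <- transform_cohort(pp, data.frame(x = 150, cst = 7, g = "a",
                                        disease = factor("u", levels = c("u", "v"))))
  expect_equal(unname(fm$x[1, "x"]), 0.5)
  expect_equal(unname(fm$x[1, "cst"]), 0)  # constant training feature

  # out-of-range values are clipped into [0, 1]
  fm2 <- transform_cohort(pp, data.frame(x = c(50, 400), cst = c(5, 5),
                                         g = c("a", "b"),
                                         disease = factor(c("u", "v"))))
  expect_equal(unname(fm2$x[, "x"]), c(0, 1))

  # unseen category: zero block plus a warning
  expect_warning(
    fm3 <- transform_cohort(pp, data.frame(x = 150, cst = 5, g = "zzz",
                                           disease = factor("u", levels = c("u", "v")))),
    "zero block")
  expect_equal(sum(fm3$x[1, c("g.a", "g.b")]), 0)
})

test_that("inverse transform recovers in-range continuous values", {
  tab <- small_cohort(n = 100, seed = 8)
  pp <- fit_preprocessor(tab, outlier_threshold = Inf)
  fm <- transform_cohort(pp, tab)
  rec <- inverse_transform(pp, fm$x)
  for (f in c("crp", "esr", "bmi")) {
    expect_equal(unname(rec[, f]), tab[[f]], tolerance = 1e-9)
  }
})

test_that("one-hot blocks sum to one for seen categories", {
  tab <- small_cohort(n = 150, seed = 9, missing_rate = 0.1)
  pp <- fit_preprocessor(tab)
  fm <- transform_cohort(pp, tab)
  for (f in c("gender", "family_history")) {
    block <- fm$x[, fm$groups == f, drop = FALSE]
    expect_true(all(abs(rowSums(block) - 1) < 1e-12))
  }
  expect_true(all(fm$x >= 0 & fm$x <= 1))
})

test_that("preprocessor state is fitted from the training partition only", {
  cohort <- small_cohort(n = 400, seed = 10)
  idx <- stratified_split(cohort$disease, seed = 1)
  pp_train <- fit_preprocessor(cohort[idx$train, ])
  pp_test <- fit_preprocessor(cohort[idx$test, ])
  expect_false(isTRUE(all.equal(pp_train$min, pp_test$min)))
  expect_false(isTRUE(all.equal(pp_train$impute_values$crp,
                                pp_test$impute_values$crp)))
})

test_that("z-score outliers are flagged and winsorized", {
  expect_equal(zscore_outliers(rep(3, 10))$mask, rep(FALSE, 10))
  expect_equal(zscore_outliers(rep(3, 10))$values, rep(3, 10))

  x <- with_seed_test(1, rnorm(100))
  spiked <- c(x, mean(x) + 10 * sd(x))
  res <- zscore_outliers(spiked, threshold = 3)
  expect_equal(which(res$mask), 101)
  m <- mean(spiked); s <- sd(spiked)
  expect_equal(res$values[101], m + 3 * s)
  expect_equal(res$values[-101], spiked[-101])

  expect_false(any(zscore_outliers(spiked, threshold = Inf)$mask))
})

test_that("stratified split hits exact sizes and per-class proportionality", {
  labels <- factor(rep(c("a", "b"), each = 5000))
  sp <- stratified_split(labels, seed = 1)
  expect_equal(length(sp$train), 8000)
  expect_equal(length(sp$validation), 1000)
  expect_equal(length(sp$test), 1000)
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_equal(sort(c(sp$train, sp$validation, sp$test)), seq_along(labels))

  single <- stratified_split(rep("only", 10), seed = 2)
  expect_equal(lengths(single[c("train", "validation", "test")]),
               c(train = 8, validation = 1, test = 1))

  expect_error(stratified_split(labels, fractions = c(0.8, 0.1)), "sum to 1")

  # per-class deviation from exact proportionality stays within one record
  for (s in 1:5) {
    y <- small_cohort(n = 997, seed = s)$disease
    sp <- stratified_split(y, seed = s)
    for (cl in levels(y)) {
      n_c <- sum(y == cl)
      for (p in c("train", "validation", "test")) {
        frac <- c(train = 0.8, validation = 0.1, test = 0.1)[[p]]
        got <- sum(y[sp[[p]]] == cl)
        expect_lte(abs(got - n_c * frac), 1)
      }
    }
  }
})

test_that("SMOTE balances classes with convex same-class interpolation", {
  # already balanced: untouched
  xb <- matrix(runif(20), 10)
  yb <- factor(rep(c("a", "b"), 5))
  out <- smote(xb, yb, seed = 1)
  expect_identical(out$x, xb)

  # two-point minority: synthetics sit on the segment, coordinates (l, l)
  x <- rbind(matrix(5 + runif(20), 10), c(0, 0), c(1, 1))
  y <- factor(c(rep("maj", 10), "min", "min"))
  res <- smote(x, y, k = 1, seed = 2)
  expect_equal(as.integer(table(res$y)[c("maj", "min")]), c(10L, 10L))
  synth <- res$x[res$y == "min", ][-(1:2), , drop = FALSE]
  expect_true(all(synth >= 0 & synth <= 1))
  expect_equal(synth[, 1], synth[, 2])

  # majority rows are never altered
  expect_identical(res$x[1:10, ], x[1:10, ])

  # synthetic points never leave the minority bounding box (convex hull in 1D coords)
  tab <- small_cohort(n = 300, seed = 11)
  pp <- fit_preprocessor(tab)
  fm <- transform_cohort(pp, tab)
  res2 <- smote(fm$x, factor(fm$y), seed = 3)
  counts <- table(res2$y)
  expect_true(all(counts == max(table(fm$y))))
  for (cl in names(counts)) {
    orig <- fm$x[fm$y == as.integer(factor(cl, levels = levels(res2$y))), , drop = FALSE]
    allc <- res2$x[res2$y == cl, , drop = FALSE]
    expect_true(all(allc >= matrix(apply(orig, 2, min), nrow(allc), ncol(allc), byrow = TRUE) - 1e-12))
    expect_true(all(allc <= matrix(apply(orig, 2, max), nrow(allc), ncol(allc), byrow = TRUE) + 1e-12))
  }

  expect_error(smote(matrix(runif(6), 3), factor(c("a", "a", "b")), seed = 1),
               "single member")
})

test_that("preprocessor state round-trips through its JSON sidecar", {
  tab <- small_cohort(n = 200, seed = 12, missing_rate = 0.1)
  pp <- fit_preprocessor(tab)
  f <- tempfile(fileext = ".json")
  preprocessor_to_json(pp, f)
  back <- preprocessor_from_json(f)
  fm1 <- transform_cohort(pp, tab)
  fm2 <- transform_cohort(back, tab)
  expect_equal(fm1$x, fm2$x, tolerance = 1e-12)
  unlink(f)
})
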