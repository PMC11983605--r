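# Metrics: confusion matrix, precision/recall/F1, AUCs, and the paired
# comparison statistics — all validated against brute-force oracles.

test_that("confusion matrix counts by hand tally", {
  cm <- confusion_matrix(c(1, 1, 2, 2), c(1, 2, 2, 2), k = 2)
  expect_equal(unname(cm), rbind(c(1, 1), c(0, 2)))

  y <- factor(c("a", "b", "c", "a"), levels = c("a", "b", "c"))
  cm2 <- confusion_matrix(y, y)
  expect_equal(unname(diag(cm2)), c(2, 1, 1))
  expect_equal(sum(cm2), 4)

  set.seed(4)
  yt <- sample(1:3, 50, replace = TRUE)
  yp <- sample(1:3, 50, replace = TRUE)
  expect_equal(sum(confusion_matrix(yt, yp, k = 3)), 50)
  expect_error(confusion_matrix(1:3, 1:2), "differ")
})

test_that("F1 is the harmonic mean of printed-scale precision and recall", {
  expect_equal(f1_score(80, 80), 80)
  expect_equal(f1_score(0, 0), 0)
  p <- runif(20, 1, 99); r <- runif(20, 1, 99)
  f <- f1_score(p, r)
  expect_true(all(f >= pmin(p, r) & f <= pmax(p, r)))
})

test_that("metrics equal brute-force recomputation on 200 random instances", {
  set.seed(7)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    n <- sample(5:50, 1)
    yt <- sample(seq_len(k), n, replace = TRUE)
    while (length(unique(yt)) < 2) yt <- sample(seq_len(k), n, replace = TRUE)
    yp <- sample(seq_len(k), n, replace = TRUE)
    cm <- confusion_matrix(yt, yp, k = k)
    got <- suppressMessages(precision_recall_f1(cm))
    want <- oracle_prf(yt, yp, k)
    expect_equal(unname(got["precision"]), want$precision, tolerance = 1e-12)
    expect_equal(unname(got["recall"]), want$recall, tolerance = 1e-12)
    expect_equal(unname(got["f1"]), want$f1, tolerance = 1e-12)
    expect_equal(100 * sum(diag(cm)) / sum(cm), want$accuracy)

    scores <- matrix(runif(n * k), n, k)
    if (any(tabulate(yt, k) == 0) || all(tabulate(yt, k) %in% c(0, n))) next
    per_class_roc <- per_class_ap <- numeric(0)
    for (cl in seq_len(k)) {
      pos <- yt == cl
      if (any(pos) && !all(pos)) {
        per_class_roc <- c(per_class_roc, oracle_auc_binary(scores[, cl], pos))
      }
      if (any(pos)) {
        per_class_ap <- c(per_class_ap, oracle_ap_binary(scores[, cl], pos))
      }
    }
    expect_equal(suppressWarnings(auc_roc(scores, yt)), mean(per_class_roc),
                 tolerance = 1e-12)
    expect_equal(auc_pr(scores, yt), mean(per_class_ap), tolerance = 1e-12)
  }
})

test_that("AUC-ROC honours separation, ties and label antisymmetry", {
  y <- c(1, 1, 1, 2, 2, 2)
  perfect <- cbind(c(9, 8, 7, 1, 2, 3), c(1, 2, 3, 9, 8, 7))
  expect_equal(auc_roc(perfect, y), 1)
  expect_equal(auc_roc(matrix(0.5, 6, 2), y), 0.5)
  expect_error(auc_roc(perfect, rep(1, 6)), "single class")

  # tie handling: midrank = +1/2 per tied (pos, neg) pair
  s <- c(0.9, 0.5, 0.5, 0.1, 0.5, 0.2)
  pos <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(aidnet:::binary_auc_roc(s, pos), oracle_auc_binary(s, pos),
               tolerance = 1e-12)

  set.seed(8)
  for (i in 1:20) {
    sc <- cbind(runif(12), runif(12))  # continuous, ties a.s. absent
    yy <- sample(1:2, 12, replace = TRUE)
    if (length(unique(yy)) < 2) next
    a <- auc_roc(sc, yy)
    flipped <- auc_roc(sc, 3L - yy)
    expect_equal(flipped, 1 - a, tolerance = 1e-12)
  }
})

test_that("AUC-PR equals prevalence for constant scores and 1 for separation", {
  y <- c(1, 1, 2, 2, 2, 2)
  perfect <- cbind(c(0.9, 0.8, 0.1, 0.2, 0.1, 0.3), c(0.1, 0.2, 0.9, 0.8, 0.7, 0.9))
  expect_equal(auc_pr(perfect, y), 1)
  # constant scores: one threshold, precision = prevalence per class
  expect_equal(auc_pr(matrix(0.4, 6, 2), y), mean(c(2 / 6, 4 / 6)))
  expect_error(auc_pr(matrix(0.4, 3, 2), c(NA, NA, NA)), "no positive")
})

test_that("metrics_report ties the pieces together consistently", {
  set.seed(9)
  yt <- factor(sample(c("RA", "SLE", "MS"), 60, replace = TRUE))
  probs <- matrix(runif(180), 60, 3, dimnames = list(NULL, levels(yt)))
  probs <- probs / rowSums(probs)
  yp <- factor(levels(yt)[max.col(probs)], levels = levels(yt))
  rep <- metrics_report(yt, yp, scores = probs)
  expect_equal(rep$accuracy, 100 * mean(yt == yp))
  expect_equal(rep$f1, mean(rep$per_class$f1))
  expect_true(rep$auc_roc >= 0 && rep$auc_roc <= 1)
  pc <- rep$per_class
  expect_true(all(pc$f1 >= pmin(pc$precision, pc$recall) - 1e-9 &
                    pc$f1 <= pmax(pc$precision, pc$recall) + 1e-9))
})

test_that("paired comparison reproduces the textbook t statistics", {
  acc <- cbind(ref = c(98, 97.5, 98.2, 97.9, 98.4),
               m1 = c(96.0, 96.0, 95.7, 96.1, 96.2))
  rep <- multi_run_compare(acc, reference = "ref")
  d <- acc[, "ref"] - acc[, "m1"]
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(rep$table$p_value[rep$table$model == "m1"], p_hand,
               tolerance = 1e-12)
  ci_hand <- qt(0.975, 4) * sd(acc[, "m1"]) / sqrt(5)
  expect_equal(rep$table$ci_half_width[rep$table$model == "m1"], ci_hand)
  expect_true(is.na(rep$table$p_value[rep$table$model == "ref"]))

  # degenerate conventions: identical runs -> p = 1; constant nonzero -> p -> 0
  same <- cbind(ref = rep(95, 5), m = rep(95, 5))
  expect_equal(multi_run_compare(same, "ref")$table$p_value[2], 1)
  expect_equal(multi_run_compare(same, "ref")$table$ci_half_width, c(0, 0))
  shifted <- cbind(ref = rep(95, 5), m = rep(94, 5))
  expect_equal(multi_run_compare(shifted, "ref")$table$p_value[2], 0)

  expect_error(multi_run_compare(acc[1, , drop = FALSE], "ref"), "2 runs")
  expect_error(multi_run_compare(acc, "nope"), "not among")

  # determinism
  expect_identical(multi_run_compare(acc, "ref"), multi_run_compare(acc, "ref"))
})
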