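test_that("metric formulas reproduce worked confusion tables", {
  perfect <- metrics(confusion_counts(TP = 28, FN = 0, TN = 98, FP = 0))
  expect_equal(unname(perfect), rep(1, 4))

  m <- metrics(confusion_counts(TP = 9, FN = 1, TN = 93, FP = 5))
  expect_equal(unname(m["sensitivity"]), 0.9000, tolerance = 1e-4)
  expect_equal(unname(m["specificity"]), 93 / 98, tolerance = 1e-4)
  expect_equal(round(unname(m["specificity"]), 4), 0.9490)
  expect_equal(round(unname(m["accuracy"]), 4), 0.9444)
  expect_equal(round(unname(m["precision"]), 4), 0.6429)

  expect_warning(u <- metrics(confusion_counts(TP = 0, FP = 0, TN = 5, FN = 2)),
                 "precision")
  expect_true(is.nan(u[["precision"]]))
  expect_equal(u[["specificity"]], 1)
  expect_error(confusion_counts(TP = -1, FP = 0, TN = 0, FN = 1),
               "non-negative")
})

test_that("stratified folds partition 126 subjects into sizes 12 and 13", {
  y <- c(rep(1, 28), rep(0, 98))
  f <- stratified_folds(y, K = 10, seed = 42)
  sizes <- as.vector(table(f))
  expect_setequal(unique(sizes), c(12, 13))
  expect_equal(sum(sizes == 13), 6)
  expect_equal(sum(sizes == 12), 4)
  # per-class balance within one
  for (cls in 0:1) {
    tab <- table(factor(f[y == cls], levels = 1:10))
    expect_lte(diff(range(tab)), 1)
  }
  # exhaustive and disjoint by construction of a single assignment vector
  expect_equal(sort(unique(f)), 1:10)
  expect_length(f, 126)
  # deterministic given seed
  expect_identical(f, stratified_folds(y, K = 10, seed = 42))
  expect_false(identical(f, stratified_folds(y, K = 10, seed = 43)))
})

test_that("balanced classes give balanced folds", {
  y <- rep(c(1, 0), each = 63)
  f <- stratified_folds(y, K = 10, seed = 7)
  for (k in 1:10) {
    d <- abs(sum(y[f == k] == 1) - sum(y[f == k] == 0))
    expect_lte(d, 1)
  }
  expect_warning(stratified_folds(c(rep(1, 3), rep(0, 20)), K = 10, seed = 1),
                 "best-effort")
})

test_that("cross-validation is reproducible and covers every subject once", {
  withr::with_seed(20, {
    X <- rbind(matrix(rnorm(40), 20, 2) + 3, matrix(rnorm(60), 30, 2) - 3)
    y <- c(rep(1, 20), rep(0, 30))
  })
  r1 <- run_cv(X, y, classifier = "svm", K = 5, repeats = 3, seed = 5,
               variance_fraction = NULL, record_folds = TRUE)
  r2 <- run_cv(X, y, classifier = "svm", K = 5, repeats = 3, seed = 5,
               variance_fraction = NULL)
  expect_identical(r1$per_repetition, r2$per_repetition)
  # perfectly separable features: accuracy 1 with zero spread
  expect_equal(unname(r1$mean["accuracy"]), 1)
  expect_equal(unname(r1$sd["accuracy"]), 0)
  # out-of-fold coverage: every subject appears in exactly one validation set
  for (rep_folds in r1$folds) {
    vals <- unlist(lapply(rep_folds, `[[`, "val"))
    expect_equal(sort(vals), 1:50)
    # no validation index ever occurs in its own fold's training set
    for (fk in rep_folds) expect_length(intersect(fk$train, fk$val), 0)
  }
})

test_that("label-permuted features score near the majority-class fraction", {
  withr::with_seed(21, {
    X <- matrix(rnorm(126 * 4), 126, 4)   # pure noise features
    y <- c(rep(1, 28), rep(0, 98))
  })
  r <- run_cv(X, y, classifier = "svm", K = 10, repeats = 10, seed = 9,
              variance_fraction = NULL)
  majority <- 98 / 126
  se <- r$sd[["accuracy"]] / sqrt(r$repeats)
  expect_lt(abs(r$mean[["accuracy"]] - majority), max(3 * se, 0.06))
})

test_that("accuracy decomposes into class-weighted sensitivity/specificity", {
  withr::with_seed(22, {
    X <- rbind(matrix(rnorm(30), 15, 2) + 1, matrix(rnorm(50), 25, 2) - 1)
    y <- c(rep(1, 15), rep(0, 25))
  })
  r <- run_cv(X, y, classifier = "gepsvm", K = 5, repeats = 4, seed = 2,
              variance_fraction = NULL)
  P <- 15; N <- 25
  for (i in seq_len(nrow(r$per_repetition))) {
    row <- r$per_repetition[i, ]
    expect_equal(row[["accuracy"]],
                 (row[["sensitivity"]] * P + row[["specificity"]] * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("PCA and classifier fits inside CV see training rows only", {
  withr::with_seed(23, {
    X <- rbind(matrix(rnorm(40), 20, 2) + 3, matrix(rnorm(40), 20, 2) - 3)
    y <- rep(c(1, 0), each = 20)
  })
  # instrument fit_pca: log the row sums of every matrix it is fitted on
  assign(".pca_fit_log", list(), envir = globalenv())
  suppressMessages(trace(
    "fit_pca", where = asNamespace("dfmorph"), print = FALSE,
    tracer = quote(.pca_fit_log[[length(.pca_fit_log) + 1]] <<-
                     rowSums(as.matrix(if (inherits(X, "feature_matrix")) X$X else X)))))
  on.exit({
    suppressMessages(untrace("fit_pca", where = asNamespace("dfmorph")))
    rm(".pca_fit_log", envir = globalenv())
  })
  r <- run_cv(X, y, classifier = "svm", K = 4, repeats = 2, seed = 3,
              variance_fraction = 0.95, record_folds = TRUE)
  fitted_rowsums <- get(".pca_fit_log", envir = globalenv())
  all_rs <- rowSums(X)
  i <- 0
  for (rep_folds in r$folds) {
    for (fk in rep_folds) {
      i <- i + 1
      seen <- fitted_rowsums[[i]]
      expect_equal(sort(seen), sort(all_rs[fk$train]))
      # no validation row's signature ever entered the fit
      expect_length(intersect(round(seen, 10), round(all_rs[fk$val], 10)), 0)
    }
  }
  expect_equal(i, length(fitted_rowsums))
})
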