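#' Confusion counts for a binary AD/NC problem
#'
#' @param TP,FP,TN,FN Non-negative integer counts; a correctly detected AD
#'   subject counts as a true positive.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

#' Classification indicators from confusion counts
#'
#' sensitivity (recall) = TP/(FN + TP); specificity = TN/(FP + TN);
#' accuracy = (TN + TP)/(FN + FP + TN + TP); precision = TP/(TP + FP).
#' A zero denominator yields `NaN` with a warning.
#'
#' @param counts A [confusion_counts()] (or a list with TP/FP/TN/FN).
#' @return Named numeric vector with `sensitivity`, `specificity`,
#'   `accuracy`, `precision`.
#' @export
metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts"))
    counts <- do.call(confusion_counts, as.list(counts)[c("TP", "FP", "TN", "FN")])
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("empty confusion table", call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what))
      return(NaN)
    }
    num / den
  }
  c(sensitivity = ratio(TP, FN + TP, "sensitivity"),
    specificity = ratio(TN, FP + TN, "specificity"),
    accuracy = (TN + TP) / total,
    precision = ratio(TP, TP + FP, "precision"))
}

#' Stratified K-fold assignment
#'
#' Randomly partitions indices into K mutually exclusive folds of nearly
#' equal size, keeping the per-class counts of any fold pair within one of
#' each other. Deterministic given `seed`.
#'
#' @param y Binary label vector (1 = AD, 0 = NC); both classes must be
#'   present and `length(y) >= K`.
#' @param K Number of folds.
#' @param seed Integer seed.
#' @param stratify If `FALSE`, plain random splitting is used.
#' @return Integer vector of fold ids in `1:K`, aligned with `y`.
#' @export
stratified_folds <- function(y, K = 10, seed = 1L, stratify = TRUE) {
  n <- length(y)
  if (n < K) stop("need at least K samples", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  folds <- integer(n)
  withr::with_seed(as.integer(seed), {
    if (stratify) {
      if (min(table(y)) < K)
        warning("a class has fewer than K members; stratification is best-effort")
      # deal the classes one after another round-robin with a single
      # rotating fold pointer: per-class counts per fold differ by <= 1
      # and, because the pointer carries over between classes, total fold
      # sizes also differ by <= 1
      start <- sample.int(K, 1)
      dealt <- 0L
      for (cls in sort(unique(y), decreasing = TRUE)) {
        idx <- sample(which(y == cls))
        folds[idx] <- ((start - 1L + dealt + seq_along(idx) - 1L) %% K) + 1L
        dealt <- dealt + length(idx)
      }
    } else {
      folds <- ((sample(n) - 1L) %% K) + 1L
    }
  })
  folds
}

#' Classifier specification for cross-validated evaluation
#'
#' @param name One of `"svm"`, `"gepsvm"`, `"tsvm"`.
#' @param ... Hyperparameters forwarded to the fit function (`C` for svm,
#'   `t` for gepsvm, `c1`/`c2` for tsvm).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("svm", "gepsvm", "tsvm"), ...) {
  name <- match.arg(name)
  structure(list(name = name, args = list(...)), class = "classifier_spec")
}

fit_classifier <- function(spec, X1, X2) {
  fun <- switch(spec$name, svm = fit_linear_svm, gepsvm = fit_gepsvm,
                tsvm = fit_tsvm)
  do.call(fun, c(list(X1, X2), spec$args))
}

predict_classifier <- function(model, X) {
  if (inherits(model, "linear_svm_model")) predict_linear_svm(model, X)
  else if (inherits(model, "gepsvm_model")) predict_gepsvm(model, X)
  else predict_tsvm(model, X)
}

#' Repeated stratified cross-validated evaluation
#'
#' For each repetition a fresh stratified K-fold split is drawn; within
#' each fold, PCA and the classifier are fitted on the training rows only
#' and the held-out rows are predicted. The out-of-fold predictions of one
#' repetition are assembled into a single full-cohort confusion table
#' (diagonal-block assembly), metrics are computed per repetition, and the
#' report carries their mean and standard deviation. AD (label 1) is the
#' positive class.
#'
#' @param X Feature matrix (rows = subjects) or a `feature_matrix`.
#' @param y Binary labels (1 = AD, 0 = NC); ignored when `X` is a
#'   `feature_matrix`.
#' @param classifier A [classifier_spec()] or one of `"svm"`, `"gepsvm"`,
#'   `"tsvm"`.
#' @param K Folds per repetition.
#' @param repeats Number of repetitions.
#' @param seed Integer seed; repetition r uses `seed + r`.
#' @param variance_fraction PCA retained-variance fraction; `NULL`
#'   disables the PCA step.
#' @param stratify Passed to [stratified_folds()].
#' @param record_folds If `TRUE`, the train/validation index sets of every
#'   fold are kept in the report (for audit).
#' @return Object of class `eval_report`: per-repetition metric matrix,
#'   `mean` and `sd` summaries, fold bookkeeping and the seed.
#' @export
run_cv <- function(X, y = NULL, classifier = "tsvm", K = 10, repeats = 50,
                   seed = 1L, variance_fraction = 0.95, stratify = TRUE,
                   record_folds = FALSE) {
  if (inherits(X, "feature_matrix")) { y <- X$y; X <- X$X }
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop("X rows must align with y", call. = FALSE)
  if (is.character(classifier)) classifier <- classifier_spec(classifier)
  stopifnot(inherits(classifier, "classifier_spec"))
  per_rep <- matrix(NA_real_, repeats, 4,
                    dimnames = list(NULL, c("sensitivity", "specificity",
                                            "accuracy", "precision")))
  fold_log <- if (record_folds) vector("list", repeats) else NULL
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(y, K = K, seed = as.integer(seed) + r,
                              stratify = stratify)
    pred <- integer(length(y))
    if (record_folds) fold_log[[r]] <- vector("list", K)
    for (k in seq_len(K)) {
      val <- which(folds == k)
      trn <- which(folds != k)
      if (length(val) == 0) next
      if (length(unique(y[trn])) < 2)
        stop(sprintf("repetition %d fold %d: training set lost a class",
                     r, k), call. = FALSE)
      Xtr <- X[trn, , drop = FALSE]
      Xva <- X[val, , drop = FALSE]
      if (!is.null(variance_fraction)) {
        pca <- fit_pca(Xtr, variance_fraction)
        Xtr <- pca_transform(pca, Xtr)
        Xva <- pca_transform(pca, Xva)
      }
      model <- tryCatch(
        fit_classifier(classifier, Xtr[y[trn] == 1, , drop = FALSE],
                       Xtr[y[trn] == 0, , drop = FALSE]),
        error = function(e) stop(sprintf(
          "repetition %d fold %d: %s", r, k, conditionMessage(e)),
          call. = FALSE))
      pred[val] <- ifelse(predict_classifier(model, Xva) == 1L, 1L, 0L)
      if (record_folds) fold_log[[r]][[k]] <- list(train = trn, val = val)
    }
    cc <- confusion_counts(TP = sum(pred == 1 & y == 1),
                           FP = sum(pred == 1 & y == 0),
                           TN = sum(pred == 0 & y == 0),
                           FN = sum(pred == 0 & y == 1))
    per_rep[r, ] <- suppressWarnings(metrics(cc))
  }
  structure(list(
    per_repetition = per_rep,
    mean = colMeans(per_rep),
    sd = apply(per_rep, 2, sd),
    K = K, repeats = repeats, seed = as.integer(seed),
    classifier = classifier$name,
    folds = fold_log
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %s, %d x %d-fold CV (seed %d)\n",
              x$classifier, x$repeats, x$K, x$seed))
  for (m in colnames(x$per_repetition))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}
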