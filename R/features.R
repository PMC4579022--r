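#' Build per-subject displacement-field feature vectors
#'
#' For every subject and every key slice, a fixed template slice (by
#' default the per-slice mean of the NC group) is rigidly aligned to the
#' subject's slice and then non-rigidly registered to it by level-set
#' motion (template as moving image, subject as reference). The resulting
#' displacement field is converted to polar form and flattened: per slice,
#' first all magnitude pixels, then all direction pixels; slices are
#' concatenated in key-slice order. Row order equals cohort order.
#'
#' @param cohort A `cohort_dataset`.
#' @param key_slices A `key_slice_set` (non-empty).
#' @param template `"mean-nc"` (default) or the id / index of a single NC
#'   subject to use as the fixed template.
#' @param params A [levelset_params()].
#' @param channels Character subset of `c("magnitude", "direction")`;
#'   which polar channels enter the feature vector.
#' @param rigid If `FALSE`, the rigid pre-alignment is skipped (useful for
#'   cohorts generated on a common grid).
#' @return Object of class `feature_matrix`: list with `X` (n_subjects x
#'   n_features), `y` (1 = AD, 0 = NC), and `layout` (data frame mapping
#'   columns to slice index, channel and pixel).
#' @export
build_features <- function(cohort, key_slices, template = "mean-nc",
                           params = levelset_params(),
                           channels = c("magnitude", "direction"),
                           rigid = TRUE) {
  stopifnot(inherits(cohort, "cohort_dataset"),
            inherits(key_slices, "key_slice_set"))
  if (length(key_slices$indices) == 0)
    stop("key_slices is empty", call. = FALSE)
  channels <- match.arg(channels, c("magnitude", "direction"),
                        several.ok = TRUE)
  pos <- keyslice_positions(key_slices, seq_len(cohort$n_slices) - 1L)
  y <- cohort_labels(cohort)
  templates <- lapply(pos, function(k) template_slice(cohort, template, k))
  n <- length(cohort$subjects)
  rows <- vector("list", n)
  layout <- NULL
  for (i in seq_len(n)) {
    feats <- list()
    for (j in seq_along(pos)) {
      k <- pos[j]
      ref <- cohort$subjects[[i]]$images[[k]]
      mov <- templates[[j]]
      if (rigid) mov <- rigid_register(mov, ref)$registered$pixels
      field <- tryCatch(
        estimate_displacement(mov, ref, params),
        error = function(e) stop(sprintf(
          "displacement estimation failed for subject %s, slice %d: %s",
          cohort$subjects[[i]]$id, key_slices$indices[j],
          conditionMessage(e)), call. = FALSE))
      pol <- to_polar(field)
      for (ch in channels)
        feats[[paste(j, ch)]] <- as.vector(pol[[ch]])
    }
    rows[[i]] <- unlist(feats, use.names = FALSE)
  }
  npix <- length(as.vector(cohort$subjects[[1]]$images[[pos[1]]]))
  layout <- do.call(rbind, lapply(seq_along(pos), function(j) {
    do.call(rbind, lapply(channels, function(ch) {
      data.frame(slice = key_slices$indices[j], channel = ch,
                 pixel = seq_len(npix) - 1L)
    }))
  }))
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(cohort$subjects, `[[`, "", "id")
  structure(list(X = X, y = y, layout = layout), class = "feature_matrix")
}

template_slice <- function(cohort, template, k) {
  y <- cohort_labels(cohort)
  if (identical(template, "mean-nc")) {
    nc <- which(y == 0)
    if (length(nc) == 0) stop("cohort has no NC subject", call. = FALSE)
    Reduce(`+`, lapply(nc, function(i) cohort$subjects[[i]]$images[[k]])) /
      length(nc)
  } else {
    cohort_slice(cohort, template, k)$pixels
  }
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$X), "subjects x", ncol(x$X), "features (",
      sum(x$y), "AD /", sum(x$y == 0), "NC )\n")
  invisible(x)
}

#' Fit a principal component model retaining a variance fraction
#'
#' Components are the eigenvectors of the column-centred covariance,
#' ordered by decreasing eigenvalue; the number retained is the smallest
#' count whose cumulative explained-variance ratio reaches
#' `variance_fraction`.
#'
#' @param X Numeric matrix (rows = samples) or a `feature_matrix`.
#' @param variance_fraction Scalar in (0, 1].
#' @return Object of class `pca_model` with `mean`, `components` (columns
#'   are orthonormal loadings), `explained_variance_ratio`, `sdev` and
#'   `n_components`.
#' @export
fit_pca <- function(X, variance_fraction = 0.95) {
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA needs at least 2 rows", call. = FALSE)
  if (variance_fraction <= 0 || variance_fraction > 1)
    stop("variance_fraction must be in (0, 1]", call. = FALSE)
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  tot <- sum(ev)
  if (tot <= .Machine$double.eps) {
    warning("zero-variance input; keeping a single trivial component")
    ratio <- rep(0, length(ev))
    ncomp <- 1L
  } else {
    ratio <- ev / tot
    ncomp <- which(cumsum(ratio) >= variance_fraction - 1e-12)[1]
    if (is.na(ncomp)) ncomp <- length(ratio)
  }
  structure(list(mean = p$center,
                 components = p$rotation[, seq_len(ncomp), drop = FALSE],
                 explained_variance_ratio = ratio[seq_len(ncomp)],
                 sdev = p$sdev[seq_len(ncomp)],
                 n_components = as.integer(ncomp)), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model:", x$n_components, "components explaining",
      sprintf("%.1f%%", 100 * sum(x$explained_variance_ratio)),
      "of variance\n")
  invisible(x)
}

#' Project rows onto a fitted principal component basis
#'
#' @param model A `pca_model`.
#' @param X Matrix (or single row vector) with the same number of columns
#'   the model was fitted on.
#' @return Matrix with `n_components` columns (centred projection).
#' @export
pca_transform <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean))
    stop("column count does not match the fitted model", call. = FALSE)
  sweep(X, 2, model$mean) %*% model$components
}
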