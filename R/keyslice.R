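#' Inter-class variance of one coronal slice
#'
#' The inter-class variance (ICV) of slice `k` is the squared l2-norm of
#' the difference between the AD-group mean slice and the NC-group mean
#' slice, computed on gray-level values directly:
#' v(k) = || mu_A(k) - mu_N(k) ||^2.
#'
#' @param cohort A `cohort_dataset` containing at least one AD and one NC
#'   subject.
#' @param k Slice number (1-based position in the stack).
#' @return Non-negative scalar.
#' @export
inter_class_variance <- function(cohort, k) {
  m <- group_mean_slices(cohort, k)
  sum((m$mu_A - m$mu_N)^2)
}

group_mean_slices <- function(cohort, k) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  y <- cohort_labels(cohort)
  if (all(y == 1) || all(y == 0))
    stop("ICV is undefined for a single-class cohort", call. = FALSE)
  if (k < 1 || k > cohort$n_slices)
    stop("slice index out of range", call. = FALSE)
  acc <- function(lbl) {
    ims <- lapply(which(y == lbl), function(i) cohort$subjects[[i]]$images[[k]])
    Reduce(`+`, ims) / length(ims)
  }
  list(mu_A = acc(1L), mu_N = acc(0L))
}

#' Inter-class variance curve over all coronal slices
#'
#' @param cohort A `cohort_dataset`.
#' @param index Optional integer vector of coronal indices attached to the
#'   slices (defaults to 0-based stack positions, matching the coronal
#'   index convention used for undersampling).
#' @return Object of class `icv_curve` with fields `v` (the ICV value per
#'   slice) and `index`.
#' @export
icv_curve <- function(cohort, index = NULL) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  v <- vapply(seq_len(cohort$n_slices),
              function(k) inter_class_variance(cohort, k), numeric(1))
  index <- index %||% (seq_len(cohort$n_slices) - 1L)
  if (length(index) != length(v))
    stop("index length must equal the number of slices", call. = FALSE)
  structure(list(v = v, index = as.integer(index)), class = "icv_curve")
}

#' Build an icv_curve from raw values
#'
#' Convenience constructor for toy curves used in tests and the CLI.
#' @param v Non-negative numeric vector of ICV values.
#' @param index Coronal indices (default 0-based).
#' @export
as_icv_curve <- function(v, index = seq_along(v) - 1L) {
  if (any(v < 0)) stop("ICV values must be >= 0", call. = FALSE)
  structure(list(v = as.numeric(v), index = as.integer(index)),
            class = "icv_curve")
}

#' @export
print.icv_curve <- function(x, ...) {
  cat("icv_curve over", length(x$v), "slices; max ICV =",
      signif(max(x$v), 4), "at index", x$index[which.max(x$v)], "\n")
  invisible(x)
}

#' Select key slices from an ICV curve
#'
#' A slice is a key slice when its ICV is strictly larger than half the
#' maximum ICV *and* it survives the undersampling rule: its coronal index
#' is congruent to `anchor` modulo `step` (with the default anchor 0,
#' "index divisible by step", which reproduces selections like
#' 60, 70, ..., 150 at step 10).
#'
#' @param curve An `icv_curve`.
#' @param step Undersampling step (integer >= 1; 1 keeps every slice
#'   passing the threshold).
#' @param anchor Offset of the undersampling grid (0 <= anchor < step).
#' @return Object of class `key_slice_set` with fields `indices` (strictly
#'   increasing coronal indices), `threshold` (half the maximum ICV) and
#'   `undersampling`. The selection may be empty, in which case a warning
#'   is emitted.
#' @export
select_key_slices <- function(curve, step = 10, anchor = 0) {
  stopifnot(inherits(curve, "icv_curve"))
  if (length(curve$v) == 0) stop("empty ICV curve", call. = FALSE)
  step <- as.integer(step)
  if (step < 1) stop("step must be >= 1", call. = FALSE)
  threshold <- max(curve$v) / 2
  keep <- curve$v > threshold & (curve$index %% step) == (anchor %% step)
  idx <- sort(curve$index[keep])
  if (length(idx) == 0)
    warning("no slice passed the key-slice rule; selection is empty")
  structure(list(indices = idx, threshold = threshold,
                 undersampling = step), class = "key_slice_set")
}

#' @export
print.key_slice_set <- function(x, ...) {
  cat("key_slice_set:", length(x$indices), "slices {",
      paste(x$indices, collapse = ", "), "}; threshold =",
      signif(x$threshold, 4), "; step =", x$undersampling, "\n")
  invisible(x)
}

# Map coronal indices of a key_slice_set back to 1-based stack positions.
keyslice_positions <- function(key_slices, curve_index) {
  pos <- match(key_slices$indices, curve_index)
  if (anyNA(pos)) stop("key slice index not present in cohort", call. = FALSE)
  pos
}
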