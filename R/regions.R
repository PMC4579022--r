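#' Detect disease-related regions by displacement-magnitude thresholding
#'
#' Keeps exactly the pixels whose polar displacement magnitude is strictly
#' greater than `T`: R = \{(x, y) : |V(x, y)| > T\}. The default T = 5
#' pixels separates deformation regarded as realistic shape change from
#' estimation noise.
#'
#' @param field A [displacement_field()] (or a `polar_field`).
#' @param T Positive magnitude threshold in pixels.
#' @param source_slice Optional coronal index recorded with the result.
#' @return Object of class `region_set` with fields `points` (a data frame
#'   with 0-based pixel coordinates `x` = column, `y` = row, and
#'   `magnitude`), `threshold_T` and `source_slice`.
#' @export
detect_regions <- function(field, T = 5, source_slice = NA_integer_) {
  if (T <= 0) stop("T must be > 0", call. = FALSE)
  mag <- if (inherits(field, "polar_field")) field$magnitude
         else to_polar(field)$magnitude
  sel <- which(mag > T, arr.ind = TRUE)
  pts <- data.frame(x = sel[, 2] - 1L, y = sel[, 1] - 1L,
                    magnitude = mag[sel])
  structure(list(points = pts, threshold_T = T,
                 source_slice = source_slice,
                 shape = dim(mag)), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set:", nrow(x$points), "points with |V| >", x$threshold_T,
      if (!is.na(x$source_slice)) paste("; slice", x$source_slice) else "",
      "\n")
  invisible(x)
}

#' Rasterise a region set into a binary mask
#'
#' @param regions A `region_set`.
#' @param shape Integer pair (rows, cols); defaults to the shape of the
#'   source field.
#' @return Binary matrix with 1 at region points; its sum equals the number
#'   of points.
#' @export
region_mask <- function(regions, shape = regions$shape) {
  stopifnot(inherits(regions, "region_set"))
  shape <- as.integer(shape)
  mask <- matrix(0L, shape[1], shape[2])
  if (nrow(regions$points) > 0) {
    if (any(regions$points$y < 0 | regions$points$y >= shape[1] |
            regions$points$x < 0 | regions$points$x >= shape[2]))
      stop("region point outside the requested shape", call. = FALSE)
    mask[cbind(regions$points$y + 1L, regions$points$x + 1L)] <- 1L
  }
  mask
}

#' Region detection between one NC and one AD subject over key slices
#'
#' For each key slice: rigidly align the NC slice to the AD slice, estimate
#' the displacement field by level-set motion (NC as moving, AD as
#' reference), and threshold its magnitude at `T`.
#'
#' @param nc_subject,ad_subject `cohort_dataset` entries (elements of
#'   `cohort$subjects`) or subject indices together with `cohort`.
#' @param cohort The `cohort_dataset` holding both subjects.
#' @param key_slices A `key_slice_set` (coronal indices are matched to the
#'   cohort's 0-based stack positions).
#' @param T Magnitude threshold (pixels).
#' @param params A [levelset_params()].
#' @return List of `region_set`, one per key slice.
#' @export
run_region_detection <- function(cohort, nc_subject, ad_subject, key_slices,
                                 T = 5, params = levelset_params()) {
  stopifnot(inherits(cohort, "cohort_dataset"),
            inherits(key_slices, "key_slice_set"))
  pos <- keyslice_positions(key_slices, seq_len(cohort$n_slices) - 1L)
  lapply(seq_along(pos), function(j) {
    k <- pos[j]
    moving <- cohort_slice(cohort, nc_subject, k)
    reference <- cohort_slice(cohort, ad_subject, k)
    reg <- rigid_register(moving, reference)
    field <- estimate_displacement(reg$registered, reference, params)
    detect_regions(field, T = T, source_slice = key_slices$indices[j])
  })
}

#' Flatten a list of region sets into one data frame
#'
#' @param region_list List of `region_set` objects.
#' @return Data frame with columns `slice`, `x`, `y`, `magnitude`.
#' @export
regions_to_df <- function(region_list) {
  rows <- lapply(region_list, function(r) {
    if (nrow(r$points) == 0) return(NULL)
    cbind(slice = r$source_slice, r$points)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(slice = integer(0), x = integer(0), y = integer(0),
                      magnitude = numeric(0))
  out
}
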