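#' Specification of a synthetic coronal brain phantom
#'
#' Defines the geometry, pathology effect sizes and noise level of a
#' synthetic 2-D coronal brain slice. A phantom contains the three tissue
#' classes whose shape change is indicative of Alzheimer's disease: a bright
#' cortical ring, a dark central lateral-ventricle region and two
#' hippocampus-like blobs. "AD-like" phantoms are produced by warping a
#' normal phantom with a known smooth deformation that enlarges the
#' ventricle by `ventricle_scale` and thins the cortical ring by
#' `cortex_scale`.
#'
#' @param image_size Side length of the square slice in pixels (>= 32).
#' @param cortex_outer_radius Outer radius of the cortical ring (pixels).
#' @param cortex_thickness Thickness of the cortical ring (pixels).
#' @param ventricle_halfwidth Half-width scale of the ventricle region (pixels).
#' @param hippocampus_radius Radius of the hippocampal blobs (pixels).
#' @param ventricle_scale Linear ventricle enlargement factor for AD
#'   subjects (>= 1; 1 means no effect).
#' @param cortex_scale Cortical-thickness scaling factor for AD subjects
#'   (0 < scale <= 1; 1 means no effect).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (intensity units; images live in \[0, 1\]).
#' @param seed Integer seed controlling all phantom randomness.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(image_size = 64, seed = 1)
#' img <- make_phantom_slice(spec)
#' range(img$pixels)
phantom_spec <- function(image_size = 128,
                         cortex_outer_radius = 0.38 * image_size,
                         cortex_thickness = 0.05 * image_size,
                         ventricle_halfwidth = 0.08 * image_size,
                         hippocampus_radius = 0.04 * image_size,
                         ventricle_scale = 1.5,
                         cortex_scale = 0.85,
                         noise_sd = 0.01,
                         seed = 1L) {
  if (!is.numeric(image_size) || image_size < 32)
    stop("image_size must be >= 32", call. = FALSE)
  if (ventricle_scale < 1)
    stop("ventricle_scale must be >= 1", call. = FALSE)
  if (cortex_scale <= 0 || cortex_scale > 1)
    stop("cortex_scale must be in (0, 1]", call. = FALSE)
  if (noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  for (p in c(cortex_outer_radius, cortex_thickness, ventricle_halfwidth,
              hippocampus_radius))
    if (p <= 0) stop("geometry parameters must be positive", call. = FALSE)
  structure(list(
    image_size = as.integer(image_size),
    cortex_outer_radius = cortex_outer_radius,
    cortex_thickness = cortex_thickness,
    ventricle_halfwidth = ventricle_halfwidth,
    hippocampus_radius = hippocampus_radius,
    ventricle_scale = ventricle_scale,
    cortex_scale = cortex_scale,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:", x$image_size, "x", x$image_size, "px;",
      "ventricle_scale", x$ventricle_scale, "; cortex_scale", x$cortex_scale,
      "; noise_sd", x$noise_sd, "; seed", x$seed, "\n")
  invisible(x)
}

# Per-subject geometry jitter: multiplicative perturbations of radii and a
# small centre shift, scaled by `subject_variation`. Drawn from an RNG
# seeded deterministically from spec$seed and the subject index.
phantom_geometry <- function(spec, subject_variation, subject_index = 0L) {
  jitter <- withr::with_seed(spec$seed + 7919L * subject_index, {
    list(rad = rnorm(4, 0, 0.03), shift = rnorm(2, 0, 1.2))
  })
  sv <- subject_variation
  c0 <- (spec$image_size - 1) / 2
  list(
    cx = c0 + sv * jitter$shift[1],
    cy = c0 + sv * jitter$shift[2],
    r_cortex = spec$cortex_outer_radius * (1 + sv * jitter$rad[1]),
    th_cortex = spec$cortex_thickness * (1 + sv * jitter$rad[2]),
    vh = spec$ventricle_halfwidth * (1 + sv * jitter$rad[3]),
    rh = spec$hippocampus_radius * (1 + sv * jitter$rad[4])
  )
}

# Geometry scaling across the simulated coronal axis: slices near the
# middle of the stack show the largest brain cross-section.
slice_radius_factor <- function(t) 0.72 + 0.28 * sin(pi * t)

# Amplitude of the AD deformation along the coronal axis: the pathology is
# confined to the central slices of the stack.
slice_effect_amplitude <- function(t) cos_taper(abs(t - 0.5), 0.15, 0.35)

# Noiseless phantom geometry at one coronal position t in [0, 1].
phantom_base_image <- function(spec, geom, t = 0.5) {
  n <- spec$image_size
  g <- coord_grids(n, n)
  f <- slice_radius_factor(t)
  dx <- g$col - geom$cx
  dy <- g$row - geom$cy
  r <- sqrt(dx^2 + dy^2)
  rc <- geom$r_cortex * f
  th <- geom$th_cortex
  vh <- geom$vh * f
  rh <- geom$rh * f
  img <- matrix(0, n, n)
  img[r <= rc] <- 0.45                      # brain interior
  img[r <= rc & r >= rc - th] <- 0.85       # cortical ring
  # ventricle: two mirrored vertical ellipses near the centre
  for (sgn in c(-1, 1)) {
    ex <- (dx - sgn * 0.8 * vh) / (0.6 * vh)
    ey <- dy / (1.4 * vh)
    img[ex^2 + ey^2 <= 1] <- 0.08
  }
  # hippocampus-like blobs below the ventricle
  for (sgn in c(-1, 1)) {
    hx <- dx - sgn * 2.6 * vh
    hy <- dy - 2.2 * vh
    img[hx^2 + hy^2 <= rh^2] <- 0.30
  }
  gauss_smooth(img, 1.0)
}

# Ground-truth backward deformation implementing ventricle enlargement and
# cortical thinning. Returns u (horizontal) and w (vertical) component
# matrices: a pixel of the AD image at p samples the normal image at p + (u, w).
phantom_deformation <- function(spec, geom, t = 0.5, amplitude = 1) {
  n <- spec$image_size
  g <- coord_grids(n, n)
  f <- slice_radius_factor(t)
  dx <- g$col - geom$cx
  dy <- g$row - geom$cy
  r <- sqrt(dx^2 + dy^2)
  rhat_x <- ifelse(r > 0, dx / r, 0)
  rhat_y <- ifelse(r > 0, dy / r, 0)
  s <- spec$ventricle_scale
  vh <- geom$vh * f
  # full-strength homothety out to r0 (covers the enlarged ventricle),
  # tapering to zero at r1
  r0 <- 1.7 * vh * s
  r1 <- r0 + 0.1 * n
  d_vent <- (1 / s - 1) * r * cos_taper(r, r0, r1)
  # cortical thinning: outer edge fixed, ring compressed towards it
  cc <- spec$cortex_scale
  rc <- geom$r_cortex * f
  th <- geom$th_cortex
  d_cort <- (r - rc) * (1 / cc - 1) * cos_taper(rc - r, 1.5 * th, 3 * th)
  d_cort[r > rc] <- 0
  d <- amplitude * (d_vent + d_cort)
  u <- gauss_smooth(d * rhat_x, 2)
  w <- gauss_smooth(d * rhat_y, 2)
  # keep the homothety exact where the taper is flat: Gaussian smoothing of
  # the linear core is identity there, so only renormalise the far field
  list(u = u, w = w)
}

#' Generate one synthetic coronal phantom slice
#'
#' @param spec A [phantom_spec()].
#' @param subject_variation Non-negative scalar scaling the per-subject
#'   geometry jitter (0 disables jitter).
#' @param t Relative coronal position in \[0, 1\] (0.5 = mid-stack).
#' @param subject_index Integer distinguishing subjects drawn from the same
#'   spec; controls the jitter realisation.
#' @param ad If `TRUE`, the slice is warped by the ground-truth AD
#'   deformation before noise is added.
#' @return A [slice_image()] with pixel values in \[0, 1\].
#' @export
make_phantom_slice <- function(spec, subject_variation = 0, t = 0.5,
                               subject_index = 0L, ad = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (subject_variation < 0)
    stop("subject_variation must be >= 0", call. = FALSE)
  geom <- phantom_geometry(spec, subject_variation, subject_index)
  img <- phantom_base_image(spec, geom, t)
  if (ad) {
    def <- phantom_deformation(spec, geom, t)
    img <- warp_matrix(img, def$u, def$w)
  }
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(
      spec$seed + 104729L * subject_index + 1299709L * round(1000 * t) +
        as.integer(ad),
      matrix(rnorm(length(img), 0, spec$noise_sd), nrow(img), ncol(img))
    )
    img <- img + noise
  }
  slice_image(pmin(pmax(img, 0), 1))
}

#' Generate a labelled synthetic cohort with ground-truth deformations
#'
#' Builds `n_nc` normal-control subjects (jittered base phantoms) and
#' `n_ad` AD subjects (the same jittered phantoms warped by a smooth
#' ground-truth deformation realising `ventricle_scale` and `cortex_scale`).
#' Each subject carries a stack of `n_slices` slices simulating the coronal
#' axis; the AD deformation amplitude is confined to the central slices.
#' Labels are 1 = AD, 0 = NC (mirroring a clinical-dementia-rating derived
#' binary label).
#'
#' @param n_ad,n_nc Number of AD and NC subjects (each >= 1).
#' @param spec A [phantom_spec()].
#' @param n_slices Slices per subject along the simulated coronal axis.
#' @param subject_variation Jitter scale passed to [make_phantom_slice()].
#' @return A list with elements `cohort` (a `cohort_dataset`) and
#'   `ground_truth`: for every AD subject, a per-slice list of
#'   `displacement_field` objects plus binary `affected_mask` matrices
#'   marking the support of the nonzero deformation.
#' @export
#' @examples
#' ph <- make_cohort(2, 3, phantom_spec(image_size = 48, seed = 3), n_slices = 4)
#' sum(cohort_labels(ph$cohort))
make_cohort <- function(n_ad, n_nc, spec = phantom_spec(), n_slices = 20,
                        subject_variation = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_ad < 1 || n_nc < 1)
    stop("n_ad and n_nc must each be >= 1", call. = FALSE)
  ts <- if (n_slices == 1) 0.5 else seq(0, 1, length.out = n_slices)
  subjects <- list()
  ground_truth <- list()
  idx <- 0L
  for (grp in list(list(label = 1L, n = n_ad, tag = "AD"),
                   list(label = 0L, n = n_nc, tag = "NC"))) {
    for (i in seq_len(grp$n)) {
      idx <- idx + 1L
      geom <- phantom_geometry(spec, subject_variation, idx)
      images <- vector("list", n_slices)
      gt <- if (grp$label == 1L) vector("list", n_slices) else NULL
      for (k in seq_len(n_slices)) {
        base <- phantom_base_image(spec, geom, ts[k])
        if (grp$label == 1L) {
          amp <- slice_effect_amplitude(ts[k])
          def <- phantom_deformation(spec, geom, ts[k], amplitude = amp)
          img <- warp_matrix(base, def$u, def$w)
          mag <- sqrt(def$u^2 + def$w^2)
          gt[[k]] <- list(
            field = displacement_field(def$u, def$w),
            affected_mask = (mag > 1e-9) * 1L
          )
        } else {
          img <- base
        }
        if (spec$noise_sd > 0) {
          img <- img + withr::with_seed(
            spec$seed + 104729L * idx + 15485863L * k,
            matrix(rnorm(length(img), 0, spec$noise_sd), nrow(img), ncol(img))
          )
        }
        images[[k]] <- pmin(pmax(img, 0), 1)
      }
      subjects[[idx]] <- list(
        id = sprintf("%s%03d", grp$tag, i),
        label = grp$label,
        cdr = grp$label,
        images = images
      )
      if (grp$label == 1L) ground_truth[[subjects[[idx]]$id]] <- gt
    }
  }
  cohort <- structure(list(
    subjects = subjects,
    n_slices = as.integer(n_slices),
    slice_positions = ts,
    spec = spec
  ), class = "cohort_dataset")
  list(cohort = cohort, ground_truth = ground_truth)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  y <- cohort_labels(x)
  cat("cohort_dataset:", length(x$subjects), "subjects (",
      sum(y), "AD /", sum(y == 0), "NC ),", x$n_slices, "slices each\n")
  invisible(x)
}

#' Label vector of a cohort (1 = AD, 0 = NC)
#' @param cohort A `cohort_dataset`.
#' @return Integer vector, one element per subject, in cohort order.
#' @export
cohort_labels <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  vapply(cohort$subjects, function(s) as.integer(s$label), integer(1))
}

#' Extract one slice of one subject as a slice_image
#' @param cohort A `cohort_dataset`.
#' @param subject Subject index (cohort order) or subject id string.
#' @param k Slice number (1-based position in the stack).
#' @export
cohort_slice <- function(cohort, subject, k) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (is.character(subject)) {
    ids <- vapply(cohort$subjects, `[[`, "", "id")
    subject <- match(subject, ids)
    if (is.na(subject)) stop("unknown subject id", call. = FALSE)
  }
  slice_image(cohort$subjects[[subject]]$images[[k]])
}

#' Write a cohort to disk as NIfTI volumes plus a manifest CSV
#'
#' Each subject's slice stack is written as a 3-D NIfTI volume (coronal
#' axis = third dimension) and a `manifest.csv` with columns
#' `subject_id, path, label, cdr` is placed alongside.
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort$subjects, function(s) {
    vol <- simplify2array(s$images)      # rows x cols x slices
    path <- file.path(dir, paste0(s$id, ".nii"))
    RNifti::writeNifti(RNifti::asNifti(vol), path)
    data.frame(subject_id = s$id, path = path,
               label = s$label, cdr = s$cdr, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
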