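#' 2-D grayscale slice image
#'
#' Lightweight container for a coronal slice: a finite numeric matrix of
#' gray levels plus an optional pixel spacing in millimetres.
#'
#' @param pixels Numeric matrix (>= 8 x 8), finite values.
#' @param spacing Numeric pair, mm per pixel along (row, col).
#' @return Object of class `slice_image`.
#' @export
slice_image <- function(pixels, spacing = c(1, 1)) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 8 || ncol(pixels) < 8)
    stop("slice_image must be at least 8 x 8", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("slice_image pixels must be finite", call. = FALSE)
  structure(list(pixels = pixels, spacing = as.numeric(spacing)),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat("slice_image:", nrow(x$pixels), "x", ncol(x$pixels),
      "px; intensity range [", signif(min(x$pixels), 3), ",",
      signif(max(x$pixels), 3), "]\n")
  invisible(x)
}

as_pixels <- function(img) {
  if (inherits(img, "slice_image")) img$pixels else as.matrix(img)
}

#' Per-pixel displacement field
#'
#' Stores the horizontal (`u`, along columns; the "real part" of the
#' complex encoding) and vertical (`w`, along rows; the "imaginary part")
#' displacement components, in pixels, on the reference-image grid. The
#' field backward-maps reference coordinates into the moving image.
#'
#' @param u,w Numeric matrices of equal shape, finite values.
#' @param iteration_log Optional numeric vector of per-iteration residuals.
#' @return Object of class `displacement_field`.
#' @export
displacement_field <- function(u, w, iteration_log = numeric(0)) {
  u <- as.matrix(u); w <- as.matrix(w)
  if (!identical(dim(u), dim(w)))
    stop("u and w must have identical dimensions", call. = FALSE)
  if (!all(is.finite(u)) || !all(is.finite(w)))
    stop("displacement components must be finite", call. = FALSE)
  structure(list(u = u, w = w, iteration_log = iteration_log),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$u^2 + x$w^2)
  cat("displacement_field:", nrow(x$u), "x", ncol(x$u),
      "px; max |V| =", signif(max(mag), 4),
      "; iterations logged:", length(x$iteration_log), "\n")
  invisible(x)
}

#' Polar (magnitude-direction) view of a displacement field
#'
#' @param field A [displacement_field()].
#' @return Object of class `polar_field` with elements `magnitude`
#'   (pixels, >= 0) and `direction` (radians in \[0, 2*pi); 0 wherever the
#'   magnitude is 0).
#' @export
to_polar <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  mag <- sqrt(field$u^2 + field$w^2)
  dir <- atan2(field$w, field$u)
  dir <- ifelse(dir < 0, dir + 2 * pi, dir)
  dir[mag == 0] <- 0
  structure(list(magnitude = mag, direction = dir), class = "polar_field")
}

#' @export
print.polar_field <- function(x, ...) {
  cat("polar_field:", nrow(x$magnitude), "x", ncol(x$magnitude),
      "px; max magnitude =", signif(max(x$magnitude), 4), "\n")
  invisible(x)
}

# Backward-warp a plain matrix by component fields (u cols, w rows).
warp_matrix <- function(img, u, w) {
  g <- coord_grids(nrow(img), ncol(img))
  bilinear_sample(img, g$row + w, g$col + u)
}

#' Warp an image through a displacement field
#'
#' Backward mapping: the output at pixel p takes the bilinear sample of
#' `image` at p + (u(p), w(p)). Out-of-bounds samples are clamped to the
#' boundary value. A zero field returns the input exactly.
#'
#' @param image A [slice_image()] or numeric matrix.
#' @param field A [displacement_field()] of the same shape.
#' @return A [slice_image()].
#' @export
warp <- function(image, field) {
  px <- as_pixels(image)
  stopifnot(inherits(field, "displacement_field"))
  if (!identical(dim(px), dim(field$u)))
    stop("image and field dimensions differ", call. = FALSE)
  out <- slice_image(warp_matrix(px, field$u, field$w))
  if (inherits(image, "slice_image")) out$spacing <- image$spacing
  out
}

#' Parameters of the level-set displacement-field solver
#'
#' @param time_step Explicit Euler step size (> 0).
#' @param max_iters Maximum number of accepted iterations (>= 1).
#' @param smooth_sigma Gaussian sigma (pixels) applied to each update force
#'   before integration (fluid-like regularisation).
#' @param field_sigma Gaussian sigma (pixels) applied to the accumulated
#'   field after each accepted step (diffusion-like regularisation; 0
#'   disables it).
#' @param grad_eps Stabiliser added to the gradient magnitude in the update
#'   denominator, as a fraction of the moving image's intensity range.
#' @param stop_tol Relative residual-change tolerance for early stopping.
#' @return Object of class `levelset_params`.
#' @export
levelset_params <- function(time_step = 0.4, max_iters = 200,
                            smooth_sigma = 1.5, field_sigma = 0.5,
                            grad_eps = 1e-3, stop_tol = 1e-4) {
  vals <- c(time_step, max_iters, smooth_sigma, grad_eps, stop_tol)
  if (any(!is.finite(vals)) || any(vals <= 0) || max_iters < 1)
    stop("all level-set parameters must be positive", call. = FALSE)
  if (!is.finite(field_sigma) || field_sigma < 0)
    stop("field_sigma must be >= 0", call. = FALSE)
  structure(list(time_step = time_step, max_iters = as.integer(max_iters),
                 smooth_sigma = smooth_sigma, field_sigma = field_sigma,
                 grad_eps = grad_eps,
                 stop_tol = stop_tol), class = "levelset_params")
}

# Rigid transform applied by backward resampling: rotate by theta about the
# image centre and translate by (tx, ty) in (col, row) pixels.
rigid_resample <- function(img, theta, tx, ty) {
  nr <- nrow(img); nc <- ncol(img)
  g <- coord_grids(nr, nc)
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  # backward map: undo translation, then rotation
  xs <- g$col - cx - tx
  ys <- g$row - cy - ty
  ct <- cos(theta); st <- sin(theta)
  src_x <- ct * xs + st * ys + cx
  src_y <- -st * xs + ct * ys + cy
  bilinear_sample(img, src_y, src_x)
}

#' Rigid pre-alignment of a moving slice to a reference slice
#'
#' Estimates the in-plane rotation and translation minimising the mean
#' squared intensity difference, starting from the identity, and returns
#' the resampled moving image. If the optimiser fails to improve on the
#' identity, the identity transform is returned.
#'
#' @param moving,reference [slice_image()] objects (or matrices) of equal
#'   shape with finite values.
#' @return List with `transform` (list: `theta` radians, `tx`, `ty` pixels),
#'   `registered` (a [slice_image()]) and `mse` (final mean squared
#'   difference).
#' @export
rigid_register <- function(moving, reference) {
  m <- as_pixels(moving); r <- as_pixels(reference)
  if (!identical(dim(m), dim(r)))
    stop("images must have the same shape", call. = FALSE)
  if (!all(is.finite(m)) || !all(is.finite(r)))
    stop("images must be finite", call. = FALSE)
  obj <- function(p) mean((rigid_resample(m, p[1], p[2], p[3]) - r)^2)
  fit <- optim(c(0, 0, 0), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 800,
                              parscale = c(0.02, 1, 1)))
  # gradient-free polish around the simplex optimum
  fit2 <- optim(fit$par, obj, method = "BFGS",
                control = list(reltol = 1e-12, maxit = 200))
  best <- if (fit2$value <= fit$value) fit2 else fit
  if (best$value > obj(c(0, 0, 0))) best <- list(par = c(0, 0, 0),
                                                 value = obj(c(0, 0, 0)))
  reg <- rigid_resample(m, best$par[1], best$par[2], best$par[3])
  list(transform = list(theta = best$par[1], tx = best$par[2],
                        ty = best$par[3]),
       registered = slice_image(reg), mse = best$value)
}

#' Level-set estimation of the displacement field between two slices
#'
#' Iteratively morphs the moving image I1 along its own gradient direction
#' until it approximates the reference I2, integrating
#' dV/dt = (I2 - I1(V)) * grad I1(V) / |grad I1(V)| with an explicit Euler
#' scheme. The update force is Gaussian-smoothed (`smooth_sigma`) before
#' integration and the accumulated field is lightly smoothed
#' (`field_sigma`) after each step; the gradient magnitude is stabilised by
#' `grad_eps` times the intensity range. A step is accepted only if the
#' residual ||I2 - I1(V)|| does not increase (otherwise the local step size
#' is halved and the update retried), so the logged residual sequence is
#' non-increasing. Iteration stops at `max_iters`, when the relative
#' residual change drops below `stop_tol`, or when the step size
#' underflows.
#'
#' @param moving,reference [slice_image()] objects (or matrices) of equal
#'   shape, assumed rigidly pre-aligned.
#' @param params A [levelset_params()].
#' @return A [displacement_field()] whose `iteration_log` holds the
#'   accepted residual sequence (non-increasing, first entry = initial
#'   residual).
#' @export
estimate_displacement <- function(moving, reference,
                                  params = levelset_params()) {
  m <- as_pixels(moving); r <- as_pixels(reference)
  stopifnot(inherits(params, "levelset_params"))
  if (!identical(dim(m), dim(r)))
    stop("images must have the same shape", call. = FALSE)
  eps <- params$grad_eps * max(diff(range(m)), .Machine$double.eps)
  u <- matrix(0, nrow(m), ncol(m))
  w <- matrix(0, nrow(m), ncol(m))
  warped <- m
  resid <- sqrt(sum((r - warped)^2))
  log <- resid
  dt <- params$time_step
  it <- 0L
  while (it < params$max_iters) {
    it <- it + 1L
    grad <- image_gradient(warped)
    gmag <- sqrt(grad$gx^2 + grad$gy^2)
    diffimg <- r - warped
    # with I1(V)(p) = I1(p + V(p)), nudging V along the warped-image
    # gradient raises the sampled intensity, so the residual-driven
    # update enters with a positive sign
    fx <- gauss_smooth(diffimg * grad$gx / (gmag + eps), params$smooth_sigma)
    fy <- gauss_smooth(diffimg * grad$gy / (gmag + eps), params$smooth_sigma)
    accepted <- FALSE
    while (dt > 1e-6) {
      u_new <- u + dt * fx
      w_new <- w + dt * fy
      if (params$field_sigma > 0) {
        u_new <- gauss_smooth(u_new, params$field_sigma)
        w_new <- gauss_smooth(w_new, params$field_sigma)
      }
      warped_new <- warp_matrix(m, u_new, w_new)
      resid_new <- sqrt(sum((r - warped_new)^2))
      if (resid_new <= resid) {
        accepted <- TRUE
        break
      }
      dt <- dt / 2
    }
    if (!accepted) break
    rel_change <- (resid - resid_new) / max(resid, .Machine$double.eps)
    u <- u_new; w <- w_new; warped <- warped_new; resid <- resid_new
    log <- c(log, resid)
    dt <- min(dt * 1.1, params$time_step)
    if (rel_change < params$stop_tol) break
  }
  displacement_field(u, w, iteration_log = log)
}
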