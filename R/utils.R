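# Internal numeric helpers shared across modules.

#' @importFrom stats dnorm optim prcomp rnorm runif sd var
#' @importFrom utils read.csv write.csv head
NULL

# Row-convolution operator for a 1-D Gaussian kernel as a dense n x n band
# matrix with replicate (clamp) boundary handling: kernel mass that would
# fall outside the grid is accumulated onto the nearest edge element, which
# is equivalent to convolving the constant-extended signal.
gauss_band_matrix <- function(n, sigma) {
  stopifnot(n >= 1, sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + seq(-r, r), 1L), n)
    for (j in seq_along(idx)) m[i, idx[j]] <- m[i, idx[j]] + k[j]
  }
  m
}

# Separable Gaussian smoothing of a matrix (replicate boundary).
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  kr <- gauss_band_matrix(nrow(img), sigma)
  kc <- gauss_band_matrix(ncol(img), sigma)
  kr %*% img %*% t(kc)
}

# Bilinear sampling of `img` at fractional (row, col) positions given in
# 0-based pixel units; positions are clamped to the image domain, so
# out-of-bounds samples take the boundary value.
bilinear_sample <- function(img, row_pos, col_pos) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(row_pos, 0), nr - 1)
  c <- pmin(pmax(col_pos, 0), nc - 1)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- img[as.vector(c0) * nr + as.vector(r0) + 1]
  i01 <- img[as.vector(c1) * nr + as.vector(r0) + 1]
  i10 <- img[as.vector(c0) * nr + as.vector(r1) + 1]
  i11 <- img[as.vector(c1) * nr + as.vector(r1) + 1]
  out <- i00 * (1 - fr) * (1 - fc) + i01 * (1 - fr) * fc +
    i10 * fr * (1 - fc) + i11 * fr * fc
  matrix(out, nr, nc)
}

# Central-difference gradient with edge replication. Returns list(gx, gy)
# where gx differentiates along columns (horizontal) and gy along rows.
image_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  jp <- pmin(seq_len(nc) + 1L, nc); jm <- pmax(seq_len(nc) - 1L, 1L)
  ip <- pmin(seq_len(nr) + 1L, nr); im <- pmax(seq_len(nr) - 1L, 1L)
  gx <- (img[, jp, drop = FALSE] - img[, jm, drop = FALSE]) / 2
  gy <- (img[ip, , drop = FALSE] - img[im, , drop = FALSE]) / 2
  list(gx = gx, gy = gy)
}

# 0-based pixel coordinate grids: col_grid varies along columns (x),
# row_grid along rows (y).
coord_grids <- function(nr, nc) {
  list(
    row = matrix(rep(0:(nr - 1), nc), nr, nc),
    col = matrix(rep(0:(nc - 1), each = nr), nr, nc)
  )
}

# Smooth raised-cosine window: 1 on [0, a], decays to 0 over [a, b].
cos_taper <- function(r, a, b) {
  w <- numeric(length(r))
  w[r <= a] <- 1
  mid <- r > a & r < b
  w[mid] <- 0.5 * (1 + cos(pi * (r[mid] - a) / (b - a)))
  w
}

`%||%` <- function(x, y) if (is.null(x)) y else x
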