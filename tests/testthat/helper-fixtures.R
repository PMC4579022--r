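# Shared fixtures, built in code at test time.

# Small noiseless phantom pair with known ground-truth deformation.
recovery_pair <- function(seed = 1, image_size = 96, ventricle_scale = 1.3,
                          cortex_scale = 0.9, noise_sd = 0) {
  spec <- phantom_spec(image_size = image_size,
                       ventricle_scale = ventricle_scale,
                       cortex_scale = cortex_scale,
                       noise_sd = noise_sd, seed = seed)
  geom <- dfmorph:::phantom_geometry(spec, 1, seed)
  base <- dfmorph:::phantom_base_image(spec, geom, 0.5)
  def <- dfmorph:::phantom_deformation(spec, geom, 0.5)
  warped <- dfmorph:::warp_matrix(base, def$u, def$w)
  if (noise_sd > 0) {
    base <- base + withr::with_seed(seed, matrix(rnorm(length(base), 0, noise_sd), nrow(base)))
    warped <- warped + withr::with_seed(seed + 1,
      matrix(rnorm(length(warped), 0, noise_sd), nrow(warped)))
  }
  mag <- sqrt(def$u^2 + def$w^2)
  list(moving = base, reference = warped, u = def$u, w = def$w,
       magnitude = mag, mask = mag > 1e-9)
}

# Two well-separated Gaussian clusters.
gaussian_clusters <- function(seed = 1, n = 20, sep = 6, p = 2) {
  withr::with_seed(seed, {
    list(X1 = matrix(rnorm(n * p), n, p) + sep / 2,
         X2 = matrix(rnorm(n * p), n, p) - sep / 2)
  })
}
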