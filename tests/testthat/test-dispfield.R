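test_that("warp with a zero field is the identity", {
  pair <- recovery_pair(seed = 2, image_size = 48)
  img <- slice_image(pair$moving)
  z <- displacement_field(matrix(0, 48, 48), matrix(0, 48, 48))
  expect_identical(warp(img, z)$pixels, img$pixels)
})

test_that("constant unit field shifts a linear ramp exactly in the interior", {
  ramp <- matrix(rep(seq(0, 1, length.out = 32), each = 32), 32, 32,
                 byrow = FALSE)
  # ramp varies along columns; field u = 1 samples one pixel to the right
  f <- displacement_field(matrix(1, 32, 32), matrix(0, 32, 32))
  out <- warp(slice_image(ramp), f)$pixels
  expect_equal(out[, 1:31], ramp[, 2:32], tolerance = 1e-12)
})

test_that("warping a phantom by its ground-truth field reproduces the AD image", {
  spec <- phantom_spec(image_size = 64, noise_sd = 0.02, seed = 13)
  ph <- make_cohort(1, 1, spec, n_slices = 3, subject_variation = 0)
  gt <- ph$ground_truth[[1]][[2]]
  base_noisy <- ph$cohort$subjects[[2]]$images[[2]]
  ad <- ph$cohort$subjects[[1]]$images[[2]]
  geom <- dfmorph:::phantom_geometry(spec, 0, 2L)
  base_clean <- dfmorph:::phantom_base_image(spec, geom, 0.5)
  rebuilt <- warp(slice_image(base_clean), gt$field)$pixels
  expect_lt(sqrt(mean((rebuilt - ad)^2)), 2 * spec$noise_sd)
})

test_that("to_polar matches hand-computed cases and the norm oracle", {
  u <- matrix(c(3, 0, -1, 0.5), 2, 2)
  w <- matrix(c(4, 0, 0, -0.5), 2, 2)
  p <- to_polar(displacement_field(u, w))
  expect_equal(p$magnitude[1, 1], 5)
  expect_equal(p$direction[1, 1], atan2(4, 3), tolerance = 1e-12)
  expect_equal(p$magnitude[2, 1], 0)
  expect_equal(p$direction[2, 1], 0)         # zero-vector convention
  expect_equal(p$direction[1, 2], pi)        # (-1, 0)
  expect_true(all(p$direction >= 0 & p$direction < 2 * pi))
  # norm-preservation oracle loop
  for (i in 1:2) for (j in 1:2)
    expect_equal(p$magnitude[i, j], sqrt(u[i, j]^2 + w[i, j]^2))
})

test_that("rigid registration recovers a known transform and never hurts", {
  spec <- phantom_spec(image_size = 96, noise_sd = 0.01, seed = 7)
  ref <- make_phantom_slice(spec, subject_variation = 1,
                            subject_index = 2)$pixels
  theta <- 5 * pi / 180
  mov <- dfmorph:::rigid_resample(ref, -theta, -3, 2)
  r <- rigid_register(mov, ref)
  # analytic inverse of the applied transform: (theta, R(theta) %*% (3, -2))
  ti <- c(cos(theta) * 3 - sin(theta) * -2, sin(theta) * 3 + cos(theta) * -2)
  expect_lt(abs(r$transform$theta - theta), 0.5 * pi / 180)
  expect_lt(abs(r$transform$tx - ti[1]), 0.5)
  expect_lt(abs(r$transform$ty - ti[2]), 0.5)
  expect_lte(r$mse, mean((mov - ref)^2))

  ident <- rigid_register(ref, ref)
  expect_equal(abs(ident$transform$theta), 0, tolerance = 1e-3)
  expect_equal(abs(ident$transform$tx), 0, tolerance = 1e-2)
})

test_that("identical and gradient-free images give a zero field", {
  pair <- recovery_pair(seed = 3, image_size = 48)
  f <- estimate_displacement(pair$moving, pair$moving,
                             levelset_params(max_iters = 20))
  expect_equal(max(abs(f$u)), 0)
  expect_equal(max(abs(f$w)), 0)
  flat <- matrix(0.5, 32, 32)
  target <- matrix(0.7, 32, 32)
  f2 <- estimate_displacement(flat, target, levelset_params(max_iters = 10))
  expect_equal(max(abs(f2$u)), 0)
  expect_equal(max(abs(f2$w)), 0)
})

test_that("a translated smooth blob is recovered to sub-pixel accuracy", {
  g <- dfmorph:::coord_grids(64, 64)
  blob <- exp(-((g$row - 32)^2 + (g$col - 32)^2) / (2 * 8^2))
  shifted <- dfmorph:::warp_matrix(blob, matrix(2, 64, 64), matrix(0, 64, 64))
  # a wider force smoothing propagates the edge-driven update across the
  # gradient-free blob top
  f <- estimate_displacement(blob, shifted,
                             levelset_params(max_iters = 400,
                                             smooth_sigma = 3))
  core <- blob > 0.3
  expect_lt(abs(mean(f$u[core]) - 2), 0.5)
  expect_lt(abs(mean(f$w[core])), 0.5)
  log <- f$iteration_log
  expect_lt(log[length(log)], 0.1 * log[1])
})

test_that("residuals are non-increasing and fields recover ground truth", {
  epes <- c(); reductions <- c()
  for (s in 1:5) {
    pair <- recovery_pair(seed = s, image_size = 96, noise_sd = 0.005)
    f <- estimate_displacement(pair$moving, pair$reference, levelset_params())
    expect_true(all(diff(f$iteration_log) <= 1e-10))
    epe <- sqrt((f$u - pair$u)^2 + (f$w - pair$w)^2)
    epes <- c(epes, mean(epe[pair$mask]))
    reductions <- c(reductions,
                    1 - (tail(f$iteration_log, 1) / f$iteration_log[1])^2)
  }
  expect_lt(max(epes), 1)
  expect_gt(min(reductions), 0.8)
})

test_that("warping by the estimate cuts the MSE on default phantoms", {
  ph <- make_cohort(1, 1, phantom_spec(image_size = 96, seed = 21),
                    n_slices = 3, subject_variation = 0)
  mov <- ph$cohort$subjects[[2]]$images[[2]]   # NC
  ref <- ph$cohort$subjects[[1]]$images[[2]]   # AD
  mse0 <- mean((mov - ref)^2)
  f <- estimate_displacement(mov, ref, levelset_params())
  mse1 <- mean((warp(slice_image(mov), f)$pixels - ref)^2)
  expect_lt(mse1, 0.2 * mse0)
})

test_that("level-set parameters are validated", {
  expect_error(levelset_params(time_step = 0), "positive")
  expect_error(levelset_params(max_iters = 0), "positive")
  expect_error(levelset_params(field_sigma = -1), "field_sigma")
  expect_error(estimate_displacement(matrix(0.1, 8, 8), matrix(0.1, 9, 9)),
               "same shape")
})
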