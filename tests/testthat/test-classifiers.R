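test_that("GEPSVM recovers an exactly fitting plane with zero eigenvalue", {
  withr::with_seed(11, {
    t1 <- runif(20, -1, 1)
    X1 <- cbind(t1, 2 * t1 + 1)        # exactly on y = 2x + 1
    X2 <- matrix(rnorm(40), 20, 2) + 3
  })
  m <- fit_gepsvm(X1, X2, t = 0)
  expect_lt(m$eigenvalues[1], 1e-10)
  # plane1 must annihilate class 1: w'x - b = 0 on every sample
  res1 <- abs(X1 %*% m$plane1$w - m$plane1$b)
  expect_lt(max(res1), 1e-6)
})

test_that("GEPSVM solves the cross-planes problem the baseline cannot", {
  d <- crossplanes_data(seed = 1)
  m <- fit_gepsvm(d$X1, d$X2, t = 1e-4)
  acc <- mean(c(predict_gepsvm(m, d$X1) == 1L, predict_gepsvm(m, d$X2) == 2L))
  expect_equal(acc, 1)
  expect_true(all(m$residuals < 1e-6))
  # brute-force check: each plane fits its own class better
  msr <- function(plane, X) mean((X %*% plane$w - plane$b)^2 / sum(plane$w^2))
  expect_lt(msr(m$plane1, d$X1), msr(m$plane1, d$X2))
  expect_lt(msr(m$plane2, d$X2), msr(m$plane2, d$X1))
  sv <- fit_linear_svm(d$X1, d$X2, C = 1)
  base <- mean(c(predict_linear_svm(sv, d$X1) == 1L,
                 predict_linear_svm(sv, d$X2) == 2L))
  expect_lte(base, 0.75)
})

test_that("GEPSVM eigenvalue is a lower bound of random Rayleigh quotients", {
  withr::with_seed(12, {
    X1 <- matrix(rnorm(60), 30, 2) + c(1, 0)
    X2 <- matrix(rnorm(60), 30, 2) - c(1, 0)
  })
  t <- 1e-4
  m <- fit_gepsvm(X1, X2, t)
  P <- crossprod(cbind(X1, -1)) + t * diag(3)
  Q <- crossprod(cbind(X2, -1))
  withr::with_seed(13, U <- matrix(rnorm(3 * 1e4), 3))
  rq <- colSums(U * (P %*% U)) / colSums(U * (Q %*% U))
  expect_lte(m$eigenvalues[1], min(rq) + 1e-10)
})

test_that("GEPSVM predictions are scale invariant and obey the tie rule", {
  d <- crossplanes_data(seed = 2)
  m1 <- fit_gepsvm(d$X1, d$X2, t = 0)
  m2 <- fit_gepsvm(5 * d$X1, 5 * d$X2, t = 0)
  X <- rbind(d$X1, d$X2)
  expect_identical(predict_gepsvm(m1, X), predict_gepsvm(m2, 5 * X))
  # equidistant point -> class 1 by the documented tie-break
  tie <- structure(list(
    plane1 = list(w = c(1, 0), b = 1), plane2 = list(w = c(0, 1), b = 1)),
    class = "gepsvm_model")
  expect_equal(predict_gepsvm(tie, c(0, 0)), 1L)
  expect_error(predict_gepsvm(m1, matrix(0, 1, 5)), "dimension")
})

test_that("GEPSVM eigen-residuals certify the generalized eigenpairs", {
  for (s in 1:5) {
    cl <- gaussian_clusters(seed = s, n = 15, sep = 3, p = 4)
    m <- fit_gepsvm(cl$X1, cl$X2, t = 1e-4)
    expect_true(all(m$residuals < 1e-6))
  }
  # rank-deficient classes on both sides with t = 0 raise with guidance
  tt <- seq(0, 1, length.out = 5)
  X1 <- cbind(tt, 2 * tt + 1)        # on a line: P singular at t = 0
  X2 <- matrix(1, 6, 2)              # constant: Q singular
  expect_error(fit_gepsvm(X1, X2, t = 0), "Tikhonov")
  # the same data succeeds once regularised
  expect_s3_class(fit_gepsvm(X1, X2, t = 1e-4), "gepsvm_model")
})

test_that("TSVM solves its QPs to optimality on separable clusters", {
  cl <- gaussian_clusters(seed = 3, n = 20, sep = 8)
  m <- fit_tsvm(cl$X1, cl$X2, 1, 1)
  acc <- mean(c(predict_tsvm(m, cl$X1) == 1L, predict_tsvm(m, cl$X2) == 2L))
  expect_equal(acc, 1)
  for (pl in m$diagnostics) {
    expect_lt(pl[["feasibility"]], 1e-6)
    expect_lt(pl[["complementarity"]], 1e-6)
  }
})

test_that("TSVM dual objective matches an independent interior-point oracle", {
  for (s in 1:3) {
    cl <- gaussian_clusters(seed = s, n = 10, sep = 3)
    cpen <- 1
    H <- cbind(cl$X1, 1); G <- cbind(cl$X2, 1)
    A <- crossprod(H) + 1e-8 * sum(diag(crossprod(H))) * diag(3)
    D <- G %*% solve(A, t(G)); D <- (D + t(D)) / 2
    mqp <- dfmorph:::solve_box_qp(D, rep(1, 10), rep(0, 10), rep(cpen, 10))
    ip <- kernlab::ipop(c = rep(-1, 10), H = D + 1e-12 * diag(10),
                        A = matrix(1, 1, 10), b = 0, l = rep(0, 10),
                        u = rep(cpen, 10), r = 10 * cpen, sigf = 10)
    a <- as.vector(kernlab::primal(ip))
    obj_or <- 0.5 * sum(a * (D %*% a)) - sum(a)
    expect_lt(abs(mqp$objective - obj_or), 1e-6)
  }
})

test_that("TSVM handles cross-planes where one plane cannot", {
  d <- crossplanes_data(seed = 1)
  m <- fit_tsvm(d$X1, d$X2, c1 = 0.1, c2 = 0.1)
  acc <- mean(c(predict_tsvm(m, d$X1) == 1L, predict_tsvm(m, d$X2) == 2L))
  expect_equal(acc, 1)
})

test_that("TSVM generalizes across draws of separable clusters", {
  correct <- 0; total <- 0
  for (s in 1:50) {
    cl <- gaussian_clusters(seed = 100 + s, n = 12, sep = 6)
    ho <- gaussian_clusters(seed = 200 + s, n = 6, sep = 6)
    m <- fit_tsvm(cl$X1, cl$X2, 1, 1)
    correct <- correct + sum(predict_tsvm(m, ho$X1) == 1L) +
      sum(predict_tsvm(m, ho$X2) == 2L)
    total <- total + 12
  }
  expect_gte(correct / total, 0.95)
})

test_that("label swap mirrors both twin models", {
  cl <- gaussian_clusters(seed = 7, n = 15, sep = 4)
  X <- rbind(cl$X1, cl$X2, matrix(rnorm(20), 10, 2))
  mt <- fit_tsvm(cl$X1, cl$X2, c1 = 1, c2 = 2)
  mt_sw <- fit_tsvm(cl$X2, cl$X1, c1 = 2, c2 = 1)
  expect_equal(mt$plane1, mt_sw$plane2, tolerance = 1e-6)
  expect_identical(predict_tsvm(mt, X), c(2L, 1L)[predict_tsvm(mt_sw, X)])
  mg <- fit_gepsvm(cl$X1, cl$X2, t = 1e-4)
  mg_sw <- fit_gepsvm(cl$X2, cl$X1, t = 1e-4)
  expect_identical(predict_gepsvm(mg, X), c(2L, 1L)[predict_gepsvm(mg_sw, X)])
})

test_that("linear SVM baseline: separable data, duality certificate, e1071", {
  cl <- gaussian_clusters(seed = 4, n = 10, sep = 8)
  m <- fit_linear_svm(cl$X1, cl$X2, C = 1)
  acc <- mean(c(predict_linear_svm(m, cl$X1) == 1L,
                predict_linear_svm(m, cl$X2) == 2L))
  expect_equal(acc, 1)
  # strong duality certifies the 20-point QP solution
  expect_lt(abs(m$primal_objective - m$dual_objective), 1e-6)
  skip_if_not_installed("e1071")
  ref <- e1071::svm(x = rbind(cl$X1, cl$X2),
                    y = factor(rep(c("a", "b"), each = 10)),
                    kernel = "linear", cost = 1, scale = FALSE)
  w_ref <- crossprod(ref$SV, ref$coefs)
  b_ref <- -ref$rho
  hinge <- pmax(0, 1 - rep(c(1, -1), each = 10) *
                  (rbind(cl$X1, cl$X2) %*% w_ref + b_ref))
  obj_ref <- 0.5 * sum(w_ref^2) + 1 * sum(hinge)
  expect_lt(abs(m$primal_objective - obj_ref), 1e-3 * (1 + abs(obj_ref)))
})

test_that("linear SVM degenerates to majority vote on constant features", {
  X1 <- matrix(1, 6, 2)
  X2 <- matrix(1, 3, 2)
  m <- fit_linear_svm(X1, X2, C = 1)
  expect_true(all(predict_linear_svm(m, rbind(X1, X2)) == 1L))
  m2 <- fit_linear_svm(X2, X1, C = 1)
  expect_true(all(predict_linear_svm(m2, rbind(X1, X2)) == 2L))
})
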