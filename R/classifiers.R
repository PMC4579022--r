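#' Fit a generalized eigenvalue proximal SVM (GEPSVM)
#'
#' Fits two non-parallel hyperplanes w'x - b = 0, each proximal to one
#' class and far from the other, by minimising the Tikhonov-regularised
#' Rayleigh quotient
#' (||X1 w - b o||^2 + t ||U||^2) / ||X2 w - b o||^2 over U = (w, b),
#' solved as the generalized eigenvalue problem P U = lambda Q U with
#' P = \[X1 -o\]'\[X1 -o\] + t I and Q = \[X2 -o\]'\[X2 -o\]. The first plane
#' is the eigenvector of the smallest generalized eigenvalue; the second
#' plane solves the role-swapped problem.
#'
#' @param X1,X2 Sample matrices (rows = samples) of class 1 and class 2.
#' @param t Tikhonov regularisation scalar (>= 0).
#' @return Object of class `gepsvm_model` with `plane1`, `plane2` (each a
#'   list with unit-norm `(w, b)`), `tikhonov_t`, `eigenvalues` (the two
#'   minimal generalized eigenvalues) and `residuals` (relative
#'   eigen-residuals ||P U - lambda Q U|| / ||U||).
#' @export
fit_gepsvm <- function(X1, X2, t = 1e-4) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (nrow(X1) < 1 || nrow(X2) < 1)
    stop("both classes must be non-empty", call. = FALSE)
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  s1 <- gep_min_eigen(X1, X2, t)
  s2 <- gep_min_eigen(X2, X1, t)
  structure(list(
    plane1 = s1$plane, plane2 = s2$plane,
    tikhonov_t = t,
    eigenvalues = c(s1$lambda, s2$lambda),
    residuals = c(s1$residual, s2$residual)
  ), class = "gepsvm_model")
}

# Smallest generalized eigenpair of (P, Q) built from proximal class A and
# distant class B, reduced to a symmetric ordinary eigenproblem through a
# Cholesky factor of whichever of Q (preferred) or P is positive definite.
gep_min_eigen <- function(XA, XB, t) {
  p <- ncol(XA)
  MA <- cbind(XA, -1)
  MB <- cbind(XB, -1)
  P <- crossprod(MA) + t * diag(p + 1)
  Q <- crossprod(MB)
  R <- tryCatch(chol(Q), error = function(e) NULL)
  if (!is.null(R)) {
    Ri <- backsolve(R, diag(p + 1))
    S <- crossprod(Ri, P %*% Ri)
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    z <- e$vectors[, p + 1]
    U <- as.vector(Ri %*% z)
    lambda <- e$values[p + 1]
  } else {
    # singular Q: reduce through P instead (smallest eigenvalue of (P, Q)
    # is the reciprocal of the largest of (Q, P)); needs P positive
    # definite, which t > 0 guarantees
    Rp <- tryCatch(chol(P), error = function(e) NULL)
    if (is.null(Rp))
      stop("both class matrices are singular; set the Tikhonov factor t > 0",
           call. = FALSE)
    Rpi <- backsolve(Rp, diag(p + 1))
    S <- crossprod(Rpi, Q %*% Rpi)
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    mu <- e$values[1]
    if (mu <= .Machine$double.eps)
      stop("degenerate problem: distant-class matrix Q is zero",
           call. = FALSE)
    z <- e$vectors[, 1]
    U <- as.vector(Rpi %*% z)
    lambda <- 1 / mu
  }
  U <- U / sqrt(sum(U^2))
  residual <- sqrt(sum((P %*% U - lambda * (Q %*% U))^2)) / sqrt(sum(U^2))
  list(plane = list(w = U[seq_len(p)], b = U[p + 1]),
       lambda = lambda, residual = residual)
}

#' Predict with a GEPSVM model
#'
#' Assigns the class of the nearer hyperplane under the norm-normalised
#' distance |w_i'x - b_i| / ||w_i||; ties break to class 1.
#'
#' @param model A `gepsvm_model`.
#' @param X Matrix of samples (rows) or a single vector.
#' @return Integer vector of class labels in \{1, 2\}.
#' @export
predict_gepsvm <- function(model, X) {
  stopifnot(inherits(model, "gepsvm_model"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != length(model$plane1$w))
    stop("feature dimension does not match the model", call. = FALSE)
  d1 <- abs(X %*% model$plane1$w - model$plane1$b) /
    sqrt(sum(model$plane1$w^2))
  d2 <- abs(X %*% model$plane2$w - model$plane2$b) /
    sqrt(sum(model$plane2$w^2))
  as.integer(ifelse(d1 <= d2, 1L, 2L))
}

#' @export
predict.gepsvm_model <- function(object, newdata, ...) {
  predict_gepsvm(object, newdata)
}

#' @export
print.gepsvm_model <- function(x, ...) {
  cat("gepsvm_model: p =", length(x$plane1$w), "; t =", x$tikhonov_t,
      "; eigenvalues =", signif(x$eigenvalues, 4),
      "; eigen-residuals =", format(x$residuals, digits = 3), "\n")
  invisible(x)
}

#' Fit a twin SVM (TSVM)
#'
#' Fits two non-parallel hyperplanes w'x + b = 0 by solving the two convex
#' quadratic programs
#' min 1/2 ||X1 w1 + o b1||^2 + c1 o'q  s.t.  -(X2 w1 + o b1) + q >= o,
#' q >= 0 (and the role-swapped problem for plane 2): each plane is
#' proximal to its own class and at least unit distance (with slack) from
#' the other. The QPs are solved through their box-constrained duals, with
#' a small ridge on the inverted Gram-type matrix for rank deficiency.
#'
#' @param X1,X2 Sample matrices (rows = samples) of class 1 and class 2.
#' @param c1,c2 Positive slack penalties of the two QPs.
#' @param ridge_frac Ridge added to \[X o\]'\[X o\] before inversion, as a
#'   fraction of its trace.
#' @return Object of class `tsvm_model` with `plane1`, `plane2`, the
#'   penalties, `slack_summaries` (total slack per QP) and `diagnostics`
#'   (per QP: duality gap, max primal-feasibility violation and max
#'   complementary-slackness violation).
#' @export
fit_tsvm <- function(X1, X2, c1 = 1, c2 = 1, ridge_frac = 1e-8) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (nrow(X1) < 1 || nrow(X2) < 1)
    stop("both classes must be non-empty", call. = FALSE)
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be > 0", call. = FALSE)
  q1 <- tsvm_qp(X1, X2, c1, ridge_frac)
  q2 <- tsvm_qp(X2, X1, c2, ridge_frac)
  structure(list(
    plane1 = q1$plane, plane2 = q2$plane,
    c1 = c1, c2 = c2,
    slack_summaries = c(q1$total_slack, q2$total_slack),
    dual_objectives = c(q1$dual_objective, q2$dual_objective),
    diagnostics = list(plane1 = q1$diag, plane2 = q2$diag)
  ), class = "tsvm_model")
}

# One TSVM quadratic program: plane proximal to XP, pushed >= 1 from XD.
tsvm_qp <- function(XP, XD, cpen, ridge_frac) {
  p <- ncol(XP)
  H <- cbind(XP, 1)
  G <- cbind(XD, 1)
  HtH <- crossprod(H)
  ridge <- ridge_frac * max(sum(diag(HtH)), .Machine$double.eps)
  A <- HtH + ridge * diag(p + 1)
  GAinvGt <- G %*% solve(A, t(G))
  D <- (GAinvGt + t(GAinvGt)) / 2
  m <- nrow(XD)
  sol <- solve_box_qp(D, rep(1, m), rep(0, m), rep(cpen, m))
  alpha <- sol$solution
  u <- as.vector(-solve(A, crossprod(G, alpha)))
  w <- u[seq_len(p)]; b <- u[p + 1]
  margins <- as.vector(G %*% u)          # X_D w + b
  slack <- pmax(0, 1 + margins)          # q_i at the optimum
  feas <- max(0, max(-(-margins + slack - 1)))   # constraint violation
  comp <- max(abs(alpha * (1 + margins - slack)),
              abs((cpen - alpha) * slack))
  primal <- 0.5 * sum((H %*% u)^2) + cpen * sum(slack)
  dual <- sum(alpha) - 0.5 * sum(alpha * (D %*% alpha))
  list(plane = list(w = w, b = b),
       total_slack = sum(slack),
       dual_objective = dual,
       diag = c(gap = primal - dual, feasibility = feas,
                complementarity = comp, kkt = sol$kkt))
}

#' Predict with a TSVM model
#'
#' Assigns the class of the nearer hyperplane under
#' |w_i'x + b_i| / ||w_i||; ties break to class 1.
#'
#' @param model A `tsvm_model`.
#' @param X Matrix of samples (rows) or a single vector.
#' @return Integer vector of class labels in \{1, 2\}.
#' @export
predict_tsvm <- function(model, X) {
  stopifnot(inherits(model, "tsvm_model"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != length(model$plane1$w))
    stop("feature dimension does not match the model", call. = FALSE)
  d1 <- abs(X %*% model$plane1$w + model$plane1$b) /
    sqrt(sum(model$plane1$w^2))
  d2 <- abs(X %*% model$plane2$w + model$plane2$b) /
    sqrt(sum(model$plane2$w^2))
  as.integer(ifelse(d1 <= d2, 1L, 2L))
}

#' @export
predict.tsvm_model <- function(object, newdata, ...) {
  predict_tsvm(object, newdata)
}

#' @export
print.tsvm_model <- function(x, ...) {
  cat("tsvm_model: p =", length(x$plane1$w), "; c1 =", x$c1, ", c2 =",
      x$c2, "; total slack =", signif(x$slack_summaries, 4), "\n")
  invisible(x)
}

#' Fit a soft-margin linear SVM (baseline classifier)
#'
#' Standard single-hyperplane maximum-margin classifier with hinge slack,
#' fitted through its dual quadratic program (box bounds plus one equality
#' constraint), solved with an interior-point QP solver.
#'
#' @param X1,X2 Sample matrices of class 1 (label +1) and class 2 (-1).
#' @param C Positive slack penalty.
#' @return Object of class `linear_svm_model` with `w`, `b`, `alpha`
#'   (dual variables in class-1-then-class-2 order), `C`, and primal /
#'   dual objective values.
#' @export
fit_linear_svm <- function(X1, X2, C = 1) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (nrow(X1) < 1 || nrow(X2) < 1)
    stop("both classes must be non-empty", call. = FALSE)
  if (C <= 0) stop("C must be > 0", call. = FALSE)
  X <- rbind(X1, X2)
  yy <- c(rep(1, nrow(X1)), rep(-1, nrow(X2)))
  n <- length(yy)
  K <- tcrossprod(X)
  scale <- max(1, sum(diag(K)) / n)
  # the dual Hessian is rank-deficient whenever p < n; escalate the ridge
  # until the interior-point solver accepts the system
  sol <- NULL
  for (jit in 10^seq(-10, -4)) {
    Hm <- (yy %o% yy) * K + jit * scale * diag(n)
    sol <- tryCatch(
      kernlab::ipop(c = rep(-1, n), H = Hm,
                    A = matrix(yy, nrow = 1), b = 0,
                    l = rep(0, n), u = rep(C, n), r = 0,
                    sigf = 9, maxiter = 100),
      error = function(e) NULL)
    if (!is.null(sol)) break
  }
  if (is.null(sol)) {
    # fully degenerate problem (e.g. identical feature rows): constant
    # majority-class prediction
    return(structure(list(w = rep(0, ncol(X)),
                          b = if (nrow(X1) >= nrow(X2)) 1 else -1,
                          alpha = rep(0, n), C = C,
                          primal_objective = C * n, dual_objective = NA_real_),
                     class = "linear_svm_model"))
  }
  alpha <- as.vector(kernlab::primal(sol))
  alpha <- pmin(pmax(alpha, 0), C)
  w <- as.vector(crossprod(X, alpha * yy))
  margins <- as.vector(X %*% w)
  svs <- which(alpha > 1e-6 * C & alpha < C * (1 - 1e-6))
  if (length(svs) > 0) {
    b <- mean(yy[svs] - margins[svs])
  } else {
    # no free support vectors: take the midpoint of the KKT interval for b
    at0 <- alpha <= 1e-6 * C
    atC <- alpha >= C * (1 - 1e-6)
    lo <- suppressWarnings(max(c((1 - margins)[yy == 1 & at0],
                                 (-1 - margins)[yy == -1 & atC])))
    hi <- suppressWarnings(min(c((1 - margins)[yy == 1 & atC],
                                 (-1 - margins)[yy == -1 & at0])))
    b <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
         else if (is.finite(lo)) lo else if (is.finite(hi)) hi else 0
  }
  if (sqrt(sum(w^2)) < 1e-10) {
    # degenerate margin (e.g. identical features, mixed labels):
    # constant majority-class prediction
    b <- if (nrow(X1) >= nrow(X2)) 1 else -1
    w <- rep(0, ncol(X))
  }
  hinge <- pmax(0, 1 - yy * (margins + b))
  primal <- 0.5 * sum(w^2) + C * sum(hinge)
  dual <- sum(alpha) - 0.5 * sum(alpha * ((yy %o% yy * K) %*% alpha))
  structure(list(w = w, b = b, alpha = alpha, C = C,
                 primal_objective = primal, dual_objective = dual),
            class = "linear_svm_model")
}

#' Predict with a linear SVM model
#'
#' @param model A `linear_svm_model`.
#' @param X Matrix of samples (rows) or a single vector.
#' @return Integer labels in \{1, 2\} (1 where w'x + b >= 0).
#' @export
predict_linear_svm <- function(model, X) {
  stopifnot(inherits(model, "linear_svm_model"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != length(model$w))
    stop("feature dimension does not match the model", call. = FALSE)
  as.integer(ifelse(as.vector(X %*% model$w) + model$b >= 0, 1L, 2L))
}

#' @export
predict.linear_svm_model <- function(object, newdata, ...) {
  predict_linear_svm(object, newdata)
}

#' @export
print.linear_svm_model <- function(x, ...) {
  cat("linear_svm_model: p =", length(x$w), "; C =", x$C,
      "; |w| =", signif(sqrt(sum(x$w^2)), 4),
      "; duality gap =", format(x$primal_objective - x$dual_objective,
                                digits = 3), "\n")
  invisible(x)
}

#' Cross-planes benchmark dataset for non-parallel-plane classifiers
#'
#' Two classes of 2-D points lying, up to uniform noise, on the crossing
#' lines y = x (class 1) and y = -x (class 2). The line parameter is drawn
#' from \[-0.9, 1\] with an exclusion zone of half-width 0.2 around the
#' crossing: points at the intersection are equidistant from both planes,
#' so any nearest-plane decision rule is undefined there, and the
#' asymmetric arms keep the bulk of each class on a single side of the
#' other class's plane, which the one-sided margin constraints of the twin
#' SVM require. No single hyperplane separates the two classes.
#'
#' @param seed Integer seed.
#' @param n Points per class.
#' @param noise Half-width of the uniform perpendicular noise.
#' @return List with matrices `X1`, `X2` (n x 2 each).
#' @export
crossplanes_data <- function(seed = 1L, n = 40, noise = 0.05) {
  withr::with_seed(as.integer(seed), {
    draw <- function() {
      t <- runif(n, -0.9, 1)
      while (any(abs(t) < 0.2))
        t[abs(t) < 0.2] <- runif(sum(abs(t) < 0.2), -0.9, 1)
      t
    }
    t1 <- draw(); t2 <- draw()
    list(X1 = cbind(t1, t1 + runif(n, -noise, noise)),
         X2 = cbind(t2, -t2 + runif(n, -noise, noise)))
  })
}
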