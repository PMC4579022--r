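# Dense convex box-constrained quadratic programming:
#   minimize 1/2 a' D a - d' a   subject to  lower <= a <= upper
# with D symmetric positive semidefinite. Projected gradient descent with
# Barzilai-Borwein steps and Armijo backtracking, accelerated by periodic
# active-set Newton polish. Used for the twin-SVM duals, whose constraints
# are pure box bounds.
solve_box_qp <- function(D, d, lower, upper, tol = 1e-10, max_iter = 5000) {
  n <- length(d)
  stopifnot(nrow(D) == n, ncol(D) == n,
            length(lower) == n, length(upper) == n, all(lower <= upper))
  proj <- function(a) pmin(pmax(a, lower), upper)
  obj <- function(a) 0.5 * sum(a * (D %*% a)) - sum(d * a)
  kkt <- function(a, g) {
    at_l <- a <= lower + 1e-12
    at_u <- a >= upper - 1e-12
    v <- abs(g)
    v[at_l] <- pmax(0, -g[at_l])
    v[at_u] <- pmax(0, g[at_u])
    max(v, 0)
  }
  newton_polish <- function(a, g) {
    at_l <- a <= lower + 1e-12 & g >= 0
    at_u <- a >= upper - 1e-12 & g <= 0
    free <- which(!(at_l | at_u))
    if (length(free) == 0) return(a)
    fixed <- setdiff(seq_len(n), free)
    rhs <- d[free]
    if (length(fixed) > 0)
      rhs <- rhs - D[free, fixed, drop = FALSE] %*% a[fixed]
    Dff <- D[free, free, drop = FALSE]
    sol <- tryCatch(solve(Dff, rhs), error = function(e)
      solve(Dff + diag(1e-10 * max(diag(Dff)), length(free)), rhs))
    cand <- a
    cand[free] <- sol
    proj(cand)
  }
  a <- proj(rep(0, n))
  g <- as.vector(D %*% a) - d
  f <- obj(a)
  ktol <- tol * (1 + max(abs(d)))
  s <- 1 / max(sum(diag(D)) / n, .Machine$double.eps)
  for (it in seq_len(max_iter)) {
    if (kkt(a, g) < ktol) break
    # Barzilai-Borwein trial step, safeguarded by projected Armijo
    # backtracking; if no decreasing step exists we are numerically
    # stationary
    step <- s
    improved <- FALSE
    while (step >= 1e-18) {
      a_new <- proj(a - step * g)
      f_new <- obj(a_new)
      if (f_new <= f - 1e-4 * sum(g * (a - a_new))) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    da <- a_new - a
    g_new <- as.vector(D %*% a_new) - d
    dg <- g_new - g
    s_bb <- sum(da * da) / max(sum(da * dg), .Machine$double.eps)
    s <- min(max(s_bb, 1e-12), 1e12)
    a <- a_new; g <- g_new; f <- f_new
    if (it %% 5 == 0) {
      cand <- newton_polish(a, g)
      f_cand <- obj(cand)
      if (f_cand < f) {
        a <- cand
        g <- as.vector(D %*% a) - d
        f <- f_cand
      }
    }
  }
  cand <- newton_polish(a, g)
  if (obj(cand) < f) {
    a <- cand
    g <- as.vector(D %*% a) - d
  }
  list(solution = a, objective = obj(a), gradient = g, kkt = kkt(a, g))
}
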