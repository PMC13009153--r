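## Independent numerical oracles used across the test files.  Everything
## here works directly on the raw map via map_step()/closures, never through
## the analytic formulas under test.

## central finite-difference Jacobian of the map
fd_jacobian <- function(model, state, h = 1e-6) {
  m <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    m[, j] <- (map_step(model, state + e) - map_step(model, state - e)) / (2 * h)
  }
  m
}

## Taylor coefficients (q20 = f_uu/2, q11 = f_uv, q30 = f_uuu/6,
## q21 = f_uuv/2, q02 = f_vv/2) of a scalar function f(u, v) around (0,0),
## by Richardson-extrapolated central differences.
fd_taylor2 <- function(f, h = 2e-3, levels = 2) {
  est <- function(h) {
    fuu <- (f(h, 0) + f(-h, 0) - 2 * f(0, 0)) / h^2
    fvv <- (f(0, h) + f(0, -h) - 2 * f(0, 0)) / h^2
    fuv <- (f(h, h) - f(h, -h) - f(-h, h) + f(-h, -h)) / (4 * h^2)
    fuuu <- (f(2 * h, 0) - 2 * f(h, 0) + 2 * f(-h, 0) - f(-2 * h, 0)) /
      (2 * h^3)
    guu <- function(v) (f(h, v) + f(-h, v) - 2 * f(0, v)) / h^2
    fuuv <- (guu(h) - guu(-h)) / (2 * h)
    c(q20 = fuu / 2, q11 = fuv, q30 = fuuu / 6, q21 = fuuv / 2, q02 = fvv / 2)
  }
  tab <- lapply(seq_len(levels), function(l) est(h / 2^(l - 1)))
  for (ord in seq_len(levels - 1)) {
    fac <- 4^ord
    tab <- lapply(seq_len(length(tab) - 1), function(l)
      (fac * tab[[l + 1]] - tab[[l]]) / (fac - 1))
  }
  tab[[1]]
}

## shifted map around the interior fixed point, one component
shifted_component <- function(model, k) {
  fp <- interior_fixed_point(model)$state
  function(u, v) (map_step(model, fp + c(u, v)) - fp)[[k]]
}

## the map conjugated by a 2x2 matrix `Tm`, centred at the interior point
conjugated_component <- function(model, Tm, k) {
  fp <- interior_fixed_point(model)$state
  Ti <- solve(Tm)
  function(X, Y) {
    uv <- as.numeric(Tm %*% c(X, Y))
    (as.numeric(Ti %*% (map_step(model, fp + uv) - fp)))[[k]]
  }
}

## classification from polyroot() moduli -- independent of char_multipliers()
polyroot_classify <- function(trace, det, tol = 1e-9) {
  m <- Mod(polyroot(c(det, -trace, 1)))
  if (any(abs(m - 1) <= tol)) return("non_hyperbolic")
  if (all(m < 1)) return("LAS")
  if (all(m > 1)) return("source")
  "saddle"
}

## MLE of a period-k cycle from the spectral radius of the Jacobian product
cycle_multiplier_mle <- function(model, cycle_points) {
  k <- nrow(cycle_points)
  P <- diag(2)
  for (i in seq_len(k)) {
    j <- jacobian_eval(model, cycle_points[i, ])
    P <- matrix(c(j$j11, j$j12, j$j21, j$j22), 2, 2, byrow = TRUE) %*% P
  }
  log(max(Mod(eigen(P, only.values = TRUE)$values))) / k
}

## random valid parameter triples with an interior point
rand_params <- function(n, seed) {
  set.seed(seed)
  data.frame(r = runif(n, 0.2, 5),
             alpha = a <- runif(n, 0.3, 3),
             gamma = runif(n, 0.05, 0.95) * a)
}

## numerically fitted center-manifold curvature Y = k1 X^2 in the flip chart
fit_manifold_k1 <- function(setup, x_range = 0.01, n_pts = 21, n_iter = 80) {
  Bt <- flip_taylor_coeffs(setup)
  b <- Bt$B12
  M <- matrix(c(b, b, -1 - Bt$B11, setup$rho2 - Bt$B11), 2, 2, byrow = TRUE)
  G1 <- conjugated_component(setup$model, M, 1)
  G2 <- conjugated_component(setup$model, M, 2)
  X <- Y <- numeric(0)
  for (X0 in seq(-x_range, x_range, length.out = n_pts)) {
    if (X0 == 0) next
    s <- c(X0, 0)
    for (t in seq_len(n_iter)) s <- c(G1(s[1], s[2]), G2(s[1], s[2]))
    X <- c(X, s[1]); Y <- c(Y, s[2])
  }
  list(k1 = unname(coef(lm(Y ~ I(X^2) - 1))[1]), X = X, Y = Y, M = M,
       G1 = G1, G2 = G2)
}
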