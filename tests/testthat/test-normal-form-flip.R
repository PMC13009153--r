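## flip analysis fixture shared across the blocks in this file
case3_setup <- flip_setup(0.5, 0.3)
case3_Bt <- flip_taylor_coeffs(case3_setup)
case3_k <- flip_center_manifold(case3_setup, case3_Bt)
case3_nf <- flip_reduced_map(case3_setup, case3_Bt, case3_k)

test_that("flip setup satisfies the Vieta identities at criticality", {
  expect_equal(case3_setup$r_c, 3.925527, tolerance = 1e-6)
  ## rho1 = -1, so rho2 = trace + 1 and (-1) * rho2 = det
  expect_lt(abs(case3_setup$rho2 * (-1) - case3_setup$det), 1e-10)
  expect_lt(abs(case3_setup$rho2 + (-1) - case3_setup$trace), 1e-10)
  expect_equal(case3_setup$rho2, 6 / 7, tolerance = 1e-9)
  ## one multiplier of J(p1) is -1 to high accuracy
  j <- jacobian_eval(case3_setup$model,
                     interior_fixed_point(case3_setup$model)$state)
  expect_lt(min(Mod(j$multipliers + 1)), 1e-8)
})

test_that("degenerate 1:2 resonance at alpha=2, gamma=1 is refused by flip_setup", {
  ## the R(-1) root exists (r = 8) but both multipliers sit at -1 there
  expect_equal(critical_r_flip(2, 1), 8, tolerance = 1e-12)
  expect_error(flip_setup(2, 1), regexp = "1:2",
               class = "rickerpp_domain_error")
})

test_that("deviation-coupling coefficients evaluate per their closed forms", {
  ## B17 = (1-x*) e^{1-x*} vanishes when x* = 1 (alpha = 2 gamma)
  s2 <- flip_setup(1, 0.5)
  expect_equal(flip_taylor_coeffs(s2)$B17, 0, tolerance = 1e-14)
  ## B18 = (x*-2) e^{1-x*}/2 at x* = 1.5
  expect_equal(case3_Bt$B18, (1.5 - 2) * exp(-0.5) / 2, tolerance = 1e-12)
  expect_equal(case3_Bt$B18, -0.1516327, tolerance = 1e-6)
})

test_that("flip Taylor coefficients match a 3-variable FD oracle including r* couplings", {
  s <- case3_setup
  fp <- interior_fixed_point(s$model)$state
  ## map component u' as a function of (u, v, rdev)
  f1 <- function(u, v, rdev) {
    m <- ricker_holling(s$r_c + rdev, s$alpha, s$gamma)
    (map_step(m, fp + c(u, v)) - fp)[[1]]
  }
  fd <- fd_taylor2(function(u, v) f1(u, v, 0))
  expect_equal(c(case3_Bt$B13, case3_Bt$B14, case3_Bt$B15, case3_Bt$B16),
               unname(fd[c("q20", "q11", "q30", "q21")]), tolerance = 1e-5)
  ## mixed u r* and u^2 r* coefficients via FD in rdev of the u-derivatives
  ## (the shifted map is linear in rdev, so the outer difference is exact)
  h <- 1e-3
  du <- function(rdev) (f1(h, 0, rdev) - f1(-h, 0, rdev)) / (2 * h)
  duu <- function(rdev) (f1(h, 0, rdev) + f1(-h, 0, rdev) - 2 * f1(0, 0, rdev)) / h^2
  hr <- 1e-3
  expect_equal((du(hr) - du(-hr)) / (2 * hr), case3_Bt$B17, tolerance = 1e-5)
  expect_equal((duu(hr) - duu(-hr)) / (2 * hr) / 2, case3_Bt$B18,
               tolerance = 1e-4)
})

test_that("center-manifold coefficients: k0 = k3 = 0, quadratic-free maps give k1 = 0", {
  expect_identical(unname(case3_k[c("k0", "k3")]), c(0, 0))
  Bt0 <- case3_Bt
  Bt0$B13 <- Bt0$B14 <- Bt0$B23 <- Bt0$B24 <- 0
  expect_equal(unname(flip_center_manifold(case3_setup, Bt0)["k1"]), 0)
})

test_that("k1 matches the curvature of the numerically attracted manifold", {
  fit <- fit_manifold_k1(case3_setup)
  expect_equal(fit$k1, unname(case3_k["k1"]), tolerance = 1e-3)
})

test_that("points on the fitted manifold stay within cubic residual after one step", {
  fit <- fit_manifold_k1(case3_setup)
  k1 <- unname(case3_k["k1"])
  for (X in c(-0.02, -0.01, 0.005, 0.015)) {
    Y <- k1 * X^2
    X1 <- fit$G1(X, Y); Y1 <- fit$G2(X, Y)
    expect_lt(abs(Y1 - k1 * X1^2), 10 * abs(X)^3)
  }
})

test_that("reduced-map coefficients reproduce the flip criticality identities", {
  ## the identities w1 = n2 and w2 = n5 + n1^2, on constructed values
  nf <- list(n1 = 0.3, n2 = 0.1, n5 = -0.2)
  expect_equal(nf$n2, 0.1)
  expect_equal(nf$n5 + nf$n1^2, -0.11)
  ## and on the computed object (independent recomputation)
  expect_identical(case3_nf$w1, case3_nf$n2)
  expect_identical(case3_nf$w2, case3_nf$n5 + case3_nf$n1^2)
})

test_that("n1 and n5 match the restriction of the map to the fitted manifold", {
  fit <- fit_manifold_k1(case3_setup)
  Lam <- function(X) fit$G1(X, fit$k1 * X^2)
  est <- function(h) {
    n1 <- (Lam(h) + Lam(-h) - 2 * Lam(0)) / (2 * h^2)
    n5 <- (Lam(2 * h) - 2 * Lam(h) + 2 * Lam(-h) - Lam(-2 * h)) / (12 * h^3)
    c(n1, n5)
  }
  e1 <- est(4e-3); e2 <- est(2e-3)
  ex <- (4 * e2 - e1) / 3
  expect_equal(ex[1], case3_nf$n1, tolerance = 1e-3)
  expect_equal(ex[2], case3_nf$n5, tolerance = 1e-3)
})

test_that("the flip at case 3 is supercritical and produces a stable 2-cycle", {
  expect_gt(case3_nf$w2, 0)
  expect_equal(case3_nf$verdict, "stable_period2")
  ## simulation just past r_c confirms the stable period-2 orbit
  m <- ricker_holling(case3_setup$r_c + 0.05, 0.5, 0.3)
  orb <- simulate(m, nsim = 300, transient = 20000)
  expect_equal(detect_period(orb), 2L)
})

test_that("period-2 amplitude grows as sqrt(r - r_c) above the flip", {
  rc <- case3_setup$r_c
  drs <- seq(0.002, 0.02, length.out = 8)
  d2 <- numeric(length(drs))
  ## continuation downward in r keeps the orbit near the cycle so modest
  ## transients suffice even close to the onset
  start <- c(0.33, 0.64)
  for (i in rev(seq_along(drs))) {
    m <- ricker_holling(rc + drs[i], 0.5, 0.3)
    orb <- simulate(m, nsim = 2, transient = 20000, x0 = start)
    s <- cbind(orb$x, orb$y)
    d2[i] <- sum((s[2, ] - s[1, ])^2) / 4
    start <- s[2, ]
  }
  fit <- lm(d2 ~ drs)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_gt(coef(fit)[["drs"]], 0)
})
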