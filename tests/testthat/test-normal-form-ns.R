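test_that("linear NS data reproduce the closed forms on the degenerate surface", {
  lin <- ns_linear_data(ricker_holling(2, 2, 1))
  expect_equal(lin$eta, 0.5, tolerance = 1e-12)
  expect_equal(lin$modulus, 1, tolerance = 1e-12)
  ## rho = exp(i pi/3) is a 6th root of unity, so no strong resonance
  expect_equal(lin$rho, complex(real = 0.5, imaginary = sqrt(3) / 2),
               tolerance = 1e-12)
  expect_true(all(lin$resonance_ok))
})

test_that("eta^2 + zeta^2 equals det(J(p1)) across random parameters", {
  ps <- rand_params(100, seed = 5)
  checked <- 0
  for (i in seq_len(nrow(ps))) {
    m <- ricker_holling(ps$r[i], ps$alpha[i], ps$gamma[i])
    lin <- tryCatch(ns_linear_data(m), rickerpp_domain_error = function(e) NULL)
    if (is.null(lin)) next   # real-multiplier regime
    j <- jacobian_eval(m, interior_fixed_point(m)$state)
    expect_lt(abs(lin$eta^2 + lin$zeta^2 - j$det), 1e-12)
    checked <- checked + 1
  }
  expect_gt(checked, 20)
})

test_that("real-multiplier regimes are refused with a flip-regime message", {
  expect_error(ns_linear_data(ricker_holling(3.5, 0.5, 0.3)),
               regexp = "flip", class = "rickerpp_domain_error")
})

test_that("transversality derivative matches a finite difference of sqrt(det)", {
  ## off the degenerate surface
  m <- ricker_holling(2, 0.6, 0.3)
  lin <- ns_linear_data(m)
  h <- 1e-6
  fd <- (ns_linear_data(m, eps = h)$modulus -
           ns_linear_data(m, eps = -h)$modulus) / (2 * h)
  expect_equal(lin$dmod_deps, fd, tolerance = 1e-6)
  ## on it: derivative identically 0 (reported, not forced positive)
  expect_lt(abs(ns_linear_data(ricker_holling(2, 2, 1))$dmod_deps), 1e-12)
})

test_that("quadratic/cubic Taylor coefficients match the finite-difference oracle", {
  for (par in list(c(2, 2, 1), c(2, 0.847723, 0.3), c(3.5, 0.5, 0.3))) {
    m <- ricker_holling(par[1], par[2], par[3])
    B <- ns_taylor_coeffs(m)
    for (k in 1:2) {
      fd <- fd_taylor2(shifted_component(m, k))
      ana <- if (k == 1) c(B$B13, B$B14, B$B15, B$B16)
             else c(B$B23, B$B24, B$B25, B$B26)
      expect_equal(ana, unname(fd[c("q20", "q11", "q30", "q21")]),
                   tolerance = 1e-5)
      expect_lt(abs(fd[["q02"]]), 1e-7)  # the map is linear in v given u
    }
  }
})

test_that("linear Taylor coefficients are the Jacobian entries (B22 = 1 at p1)", {
  m <- ricker_holling(3.598768, 2, 1)
  B <- ns_taylor_coeffs(m)
  j <- jacobian_eval(m, interior_fixed_point(m)$state)
  expect_equal(B$B11, j$j11, tolerance = 1e-14)
  expect_equal(B$B12, -1, tolerance = 1e-14)  # -alpha x*/(1+x*) at x*=1
  expect_equal(B$B21, j$j21, tolerance = 1e-14)
  expect_equal(B$B22, 1, tolerance = 1e-14)
})

test_that("transformed-map coefficients A match the FD oracle on the conjugated map", {
  for (par in list(c(2, 0.847723, 0.3), c(2, 2, 1))) {
    m <- ricker_holling(par[1], par[2], par[3])
    nf <- ns_normal_form(m)
    eta <- nf$linear$eta; zeta <- nf$linear$zeta
    Tm <- matrix(c(nf$B$B12, 0, eta - nf$B$B11, -zeta), 2, 2, byrow = TRUE)
    ## linear part must be the rotation-scaling (eta, -zeta; zeta, eta)
    G1 <- conjugated_component(m, Tm, 1)
    G2 <- conjugated_component(m, Tm, 2)
    h <- 1e-7
    expect_equal((G1(h, 0) - G1(-h, 0)) / (2 * h), eta, tolerance = 1e-6)
    expect_equal((G2(h, 0) - G2(-h, 0)) / (2 * h), zeta, tolerance = 1e-6)
    expect_equal((G1(0, h) - G1(0, -h)) / (2 * h), -zeta, tolerance = 1e-6)
    ## nonlinear coefficients
    fd1 <- fd_taylor2(G1); fd2 <- fd_taylor2(G2)
    rel <- function(a, b) abs(a - b) / max(abs(b), 1e-8)
    expect_lt(rel(nf$A$A13, fd1[["q20"]]), 1e-5)
    expect_lt(rel(nf$A$A12, fd1[["q11"]]), 1e-5)
    expect_lt(rel(nf$A$A11, fd1[["q30"]]), 1e-4)
    expect_lt(rel(nf$A$A14, fd1[["q21"]]), 1e-4)
    expect_lt(rel(nf$A$A23, fd2[["q20"]]), 1e-5)
    expect_lt(rel(nf$A$A22, fd2[["q11"]]), 1e-4)
    expect_lt(rel(nf$A$A21, fd2[["q30"]]), 1e-4)
    expect_lt(rel(nf$A$A24, fd2[["q21"]]), 1e-3)
    ## pure-Y second derivatives vanish in this normal form
    expect_lt(abs(fd1[["q02"]]), 1e-6)
    expect_lt(abs(fd2[["q02"]]), 1e-6)
  }
})

test_that("delta coefficients and chi follow their defining combinations", {
  ## delta11 = (A13 + i A23)/2
  A <- list(A11 = 0, A12 = 0, A13 = 2, A14 = 0,
            A21 = 0, A22 = 0, A23 = 4, A24 = 0)
  dc <- rickerpp:::ns_delta_chi(A, complex(real = 0.5, imaginary = sqrt(3) / 2))
  expect_equal(dc$delta11, complex(real = 1, imaginary = 2))
  ## a linear map has zero normal-form data
  A0 <- as.list(setNames(rep(0, 8), names(A)))
  dc0 <- rickerpp:::ns_delta_chi(A0, complex(real = 0.6, imaginary = 0.8))
  expect_true(all(vapply(dc0[1:4], function(z) Mod(z) == 0, logical(1))))
  expect_identical(dc0$chi, 0)
  ## all-zero B propagates to all-zero A
  Bz <- list(B11 = 0.3, B12 = -1, B13 = 0, B14 = 0, B15 = 0, B16 = 0,
             B21 = 0.2, B22 = 1, B23 = 0, B24 = 0, B25 = 0, B26 = 0)
  Az <- rickerpp:::ns_A_from_B(Bz, eta = 0.4, zeta = 0.7)
  expect_true(all(abs(unlist(Az)) == 0))
})

test_that("chi agrees with the FD-oracle recomputation and is conjugation invariant", {
  m <- ricker_holling(2, 0.847723, 0.3)
  nf <- ns_normal_form(m)
  expect_true(is.finite(nf$chi))
  ## recompute chi from FD Taylor coefficients of the conjugated map;
  ## three Richardson levels push the oracle below 1e-7 relative
  eta <- nf$linear$eta; zeta <- nf$linear$zeta
  Tm <- matrix(c(nf$B$B12, 0, eta - nf$B$B11, -zeta), 2, 2, byrow = TRUE)
  fd1 <- fd_taylor2(conjugated_component(m, Tm, 1), h = 0.02, levels = 3)
  fd2 <- fd_taylor2(conjugated_component(m, Tm, 2), h = 0.02, levels = 3)
  A_fd <- list(A11 = fd1[["q30"]], A12 = fd1[["q11"]], A13 = fd1[["q20"]],
               A14 = fd1[["q21"]],
               A21 = fd2[["q30"]], A22 = fd2[["q11"]], A23 = fd2[["q20"]],
               A24 = fd2[["q21"]])
  chi_fd <- rickerpp:::ns_delta_chi(A_fd, nf$linear$rho)$chi
  expect_equal(nf$chi, chi_fd, tolerance = 1e-6)
  ## conjugate branch (zeta -> -zeta, rho -> conj(rho)) gives the same chi
  A_conj <- rickerpp:::ns_A_from_B(nf$B, eta, -zeta)
  chi_conj <- rickerpp:::ns_delta_chi(A_conj, Conj(nf$linear$rho))$chi
  expect_equal(nf$chi, chi_conj, tolerance = 1e-8)
})

test_that("strong resonances are refused with the resonance order named", {
  ## alpha = 2, gamma = 1: trace = 2 - r/2, det = 1
  ## r = 6 -> rho = exp(2 pi i/3) (rho^3 = 1); r = 4 -> rho = i (rho^4 = 1)
  expect_error(ns_normal_form(ricker_holling(6, 2, 1)),
               regexp = "rho\\^3", class = "rickerpp_domain_error")
  expect_error(ns_normal_form(ricker_holling(4, 2, 1)),
               regexp = "rho\\^4", class = "rickerpp_domain_error")
})

test_that("chi < 0 on the degenerate surface comes with a bounded invariant-curve orbit", {
  m <- ricker_holling(2, 0.847723, 0.3)
  nf <- ns_normal_form(m)
  expect_lt(nf$chi, 0)
  fp <- interior_fixed_point(m)$state
  orb <- simulate(m, nsim = 1e5, x0 = fp + c(0.01, 0), transient = 0)
  expect_true(is.na(attr(orb, "diverged")))
  ## stays on a small closed-curve-like set around p1
  expect_lt(max(abs(orb$x - fp[1])), 0.05)
  expect_lt(max(abs(orb$y - fp[2])), 0.2)
})
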