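#' Set up the flip (period-doubling) analysis at the interior fixed point
#'
#' Locates the critical rate \eqn{r_c} (via [critical_r_flip()]), where one
#' multiplier of \eqn{J(p_1)} equals \eqn{-1}, and extracts the second
#' multiplier \eqn{\rho_2 = \mathrm{trace} + 1} (Vieta).  A generic flip
#' requires \eqn{|\rho_2| \neq 1}; the degenerate 1:2-resonance case (both
#' multipliers at \eqn{-1}, e.g. \eqn{\alpha = 2, \gamma = 1}) is rejected
#' with a domain error.
#'
#' @param alpha,gamma model parameters with `alpha > gamma` and a flip root
#'   in `r`.
#' @param tol tolerance on \eqn{|\rho_1 + 1|} and on the
#'   \eqn{|\rho_2| \neq 1} check.
#' @return Class `"ricker_holling_flip_setup"`: `alpha`, `gamma`, `r_c`,
#'   `rho2`, `trace`, `det`, `xstar`, `ystar`, `model` (at `r_c`).
#' @examples
#' flip_setup(0.5, 0.3)
#' @export
flip_setup <- function(alpha, gamma, tol = 1e-8) {
  r_c <- critical_r_flip(alpha, gamma)
  model <- ricker_holling(r_c, alpha, gamma)
  td <- p1_trace_det(r_c, alpha, gamma)
  tr <- td[["trace"]]; de <- td[["det"]]
  ## R(-1) = 0 means -1 is a root; the other root is trace + 1.
  if (abs(1 + tr + de) > tol)
    abort_domain("internal inconsistency: R(-1) != 0 at the computed r_c")
  rho2 <- tr + 1
  if (abs(abs(rho2) - 1) <= tol)
    abort_domain(paste(
      "degenerate flip: the second multiplier lies on the unit circle",
      sprintf("(rho2 = %.8g), a 1:2 resonance rather than a generic", rho2),
      "period-doubling"))
  st <- interior_state(model)
  structure(list(alpha = alpha, gamma = gamma, r_c = r_c, rho2 = rho2,
                 trace = tr, det = de, xstar = st[1], ystar = st[2],
                 model = model),
            class = "ricker_holling_flip_setup")
}

#' Taylor coefficients for the flip expansion
#'
#' The same shifted-map coefficients as [ns_taylor_coeffs()], evaluated at
#' the critical rate \eqn{r_c}, augmented with the deviation-coupling terms
#' \eqn{\tilde B_{17} = (1-x^*)e^{1-x^*}} (coefficient of \eqn{u\,r^*}) and
#' \eqn{\tilde B_{18} = (x^*-2)e^{1-x^*}/2} (coefficient of
#' \eqn{u^2 r^*}), where \eqn{r^*} is the deviation of the growth rate from
#' \eqn{r_c}.
#'
#' @param setup a [flip_setup()] object.
#' @return Named list `B11..B26`, `B17`, `B18`, `xstar`, `ystar`.
#' @export
flip_taylor_coeffs <- function(setup) {
  stopifnot(inherits(setup, "ricker_holling_flip_setup"))
  B <- taylor_B(setup$r_c, setup$alpha, setup$gamma, setup$xstar, setup$ystar)
  ee <- exp(1 - setup$xstar)
  B$B17 <- (1 - setup$xstar) * ee
  B$B18 <- (setup$xstar - 2) * ee / 2
  B
}

## Coefficients of the nonlinear parts (Psi~, Phi~) in the flip eigenbasis
## (u,v) = M (X,Y), M = (B12, B12; -1-B11, rho2-B11).  With
## c1 = -(1+B11), c2 = rho2 - B11, D = B12 (1 + rho2):
##   Psi~ = q1 u^2 + q2 uv + q3 u^3 + q4 u^2 v + q5 u r* + q6 u^2 r*
##   Phi~ = p1 u^2 + p2 uv + p3 u^3 + p4 u^2 v + p5 u r* + p6 u^2 r*
flip_chart_coefs <- function(B, rho2) {
  b <- B$B12
  c1 <- -(1 + B$B11)
  c2 <- rho2 - B$B11
  D <- b * (1 + rho2)
  list(b = b, c1 = c1, c2 = c2, D = D,
       q1 = (c2 * B$B13 - b * B$B23) / D,
       q2 = (c2 * B$B14 - b * B$B24) / D,
       q3 = (c2 * B$B15 - b * B$B25) / D,
       q4 = (c2 * B$B16 - b * B$B26) / D,
       q5 = c2 * B$B17 / D,
       q6 = c2 * B$B18 / D,
       p1 = ((1 + B$B11) * B$B13 + b * B$B23) / D,
       p2 = ((1 + B$B11) * B$B14 + b * B$B24) / D,
       p5 = (1 + B$B11) * B$B17 / D,
       p6 = (1 + B$B11) * B$B18 / D)
}

#' Center-manifold coefficients of the flip reduction
#'
#' The center manifold through the origin of the extended system
#' \eqn{(X, Y, r^*)} is \eqn{Y = Z(X, r^*) = k_0 r^* + k_1 X^2 + k_2 X r^*
#' + k_3 (r^*)^2} with \eqn{k_0 = k_3 = 0}; invariance at order \eqn{X^2}
#' and \eqn{X r^*} yields
#' \deqn{k_1 = \frac{(1+\tilde B_{11})[\tilde B_{14}(1+\tilde B_{11}) -
#'   \tilde B_{12}(\tilde B_{13}-\tilde B_{24})] -
#'   \tilde B_{23}\tilde B_{12}^2}{\rho_2^2 - 1}, \qquad
#'   k_2 = \frac{-(1+\tilde B_{11})\tilde B_{17}}{(1+\rho_2)^2}.}
#'
#' @param setup a [flip_setup()] object.
#' @param Bt coefficients from [flip_taylor_coeffs()].
#' @return Named numeric `c(k0, k1, k2, k3)`.
#' @export
flip_center_manifold <- function(setup, Bt = flip_taylor_coeffs(setup)) {
  stopifnot(inherits(setup, "ricker_holling_flip_setup"))
  rho2 <- setup$rho2
  if (abs(rho2^2 - 1) < 1e-12)
    abort_domain("center manifold undefined: rho2^2 = 1")
  cc <- flip_chart_coefs(Bt, rho2)
  ## invariance at X^2:  k1 = Phi~_{X^2} / (1 - rho2)
  PhiX2 <- cc$p1 * cc$b^2 + cc$p2 * cc$b * cc$c1
  k1 <- PhiX2 / (1 - rho2)
  ## invariance at X r*: -k2 = rho2 k2 + Phi~_{X r*}
  k2 <- -(1 + Bt$B11) * Bt$B17 / (1 + rho2)^2
  c(k0 = 0, k1 = unname(k1), k2 = unname(k2), k3 = 0)
}

#' Reduced one-dimensional map on the center manifold
#'
#' Substituting \eqn{Y = Z(X, r^*)} into the transformed system gives the
#' reduced map
#' \deqn{L(X) = -X + n_1 X^2 + n_2 X r^* + n_3 X^2 r^* + n_4 X (r^*)^2 +
#'   n_5 X^3 + O(4),}
#' whose flip criticality quantities are \eqn{\varpi_1 = n_2} (parameter
#' transversality) and \eqn{\varpi_2 = n_5 + n_1^2} (direction/stability):
#' \eqn{\varpi_2 > 0} gives stable period-2 points (supercritical flip),
#' \eqn{\varpi_2 < 0} unstable ones.
#'
#' @param setup a [flip_setup()] object.
#' @param Bt coefficients from [flip_taylor_coeffs()].
#' @param km center-manifold coefficients from [flip_center_manifold()].
#' @param degenerate_tol threshold below which \eqn{|\varpi_1|} or
#'   \eqn{|\varpi_2|} is treated as degenerate.
#' @return Class `"ricker_holling_flip_nf"`: `n1..n5`, `w1`, `w2`,
#'   `verdict` (one of `"stable_period2"`, `"unstable_period2"`,
#'   `"degenerate"`).
#' @export
flip_reduced_map <- function(setup, Bt = flip_taylor_coeffs(setup),
                             km = flip_center_manifold(setup, Bt),
                             degenerate_tol = 1e-10) {
  stopifnot(inherits(setup, "ricker_holling_flip_setup"))
  cc <- flip_chart_coefs(Bt, setup$rho2)
  b <- cc$b; c1 <- cc$c1; c2 <- cc$c2
  k1 <- km[["k1"]]; k2 <- km[["k2"]]
  ## L(X) = -X + Psi~(u(X, Z), v(X, Z), r*), collected by order:
  n1 <- cc$q1 * b^2 + cc$q2 * b * c1
  n2 <- cc$q5 * b
  n3 <- cc$q6 * b^2 + cc$q5 * b * k1 +
    cc$q1 * 2 * b^2 * k2 + cc$q2 * b * k2 * (c1 + c2)
  n4 <- cc$q5 * b * k2
  n5 <- cc$q3 * b^3 + cc$q4 * b^2 * c1 +
    cc$q1 * 2 * b^2 * k1 + cc$q2 * b * k1 * (c1 + c2)
  w1 <- n2
  w2 <- n5 + n1^2
  verdict <- if (abs(w1) < degenerate_tol || abs(w2) < degenerate_tol) {
    warning("flip normal form is degenerate (|w1| or |w2| below tolerance)")
    "degenerate"
  } else if (w2 > 0) "stable_period2" else "unstable_period2"
  structure(list(n1 = n1, n2 = n2, n3 = n3, n4 = n4, n5 = n5,
                 w1 = w1, w2 = w2, verdict = verdict),
            class = "ricker_holling_flip_nf")
}

#' Full flip (period-doubling) analysis
#'
#' Convenience pipeline: [flip_setup()], [flip_taylor_coeffs()],
#' [flip_center_manifold()], [flip_reduced_map()].
#'
#' @inheritParams flip_setup
#' @return Class `"ricker_holling_flip"` collecting all pieces.
#' @examples
#' flip_analysis(0.5, 0.3)
#' @export
flip_analysis <- function(alpha, gamma) {
  setup <- flip_setup(alpha, gamma)
  Bt <- flip_taylor_coeffs(setup)
  km <- flip_center_manifold(setup, Bt)
  nf <- flip_reduced_map(setup, Bt, km)
  structure(list(setup = setup, Bt = Bt, k = km, nf = nf),
            class = "ricker_holling_flip")
}

#' @export
print.ricker_holling_flip <- function(x, ...) {
  cat("Flip (period-doubling) bifurcation at the interior fixed point\n")
  cat(sprintf("  alpha = %.6g, gamma = %.6g\n", x$setup$alpha, x$setup$gamma))
  cat(sprintf("  r_c = %.8g, rho2 = %.8g\n", x$setup$r_c, x$setup$rho2))
  cat(sprintf("  k1 = %.7g, k2 = %.7g\n", x$k[["k1"]], x$k[["k2"]]))
  cat(sprintf("  n1..n5 = %s\n",
              paste(format(unlist(x$nf[c("n1","n2","n3","n4","n5")]),
                           digits = 6), collapse = ", ")))
  cat(sprintf("  w1 = %.7g, w2 = %.7g -> %s\n",
              x$nf$w1, x$nf$w2, x$nf$verdict))
  invisible(x)
}
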