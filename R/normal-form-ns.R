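#' Linear Neimark-Sacker data at the interior fixed point
#'
#' With \eqn{r = r^* + \epsilon}, the multipliers at \eqn{p_1} are
#' \eqn{\rho_{1,2} = \eta \pm i\zeta} with \eqn{\eta = \mathrm{trace}/2}
#' and \eqn{\zeta = \sqrt{4\det - \mathrm{trace}^2}/2}, so
#' \eqn{|\rho| = \sqrt{\det}}.  The radial transversality derivative is
#' \eqn{d|\rho|/d\epsilon = c_q / (2\sqrt{\det})} where
#' \eqn{\det = 1 + c_q(r^*+\epsilon)}; on the degenerate surface
#' \eqn{\gamma^2-\gamma+\alpha^2-2\alpha\gamma=0} it is identically 0 and
#' the computed value is reported without enforcing positivity.
#'
#' @param model a [ricker_holling()] model (`model$r` is taken as
#'   \eqn{r^*}); requires `alpha > gamma` and a complex multiplier pair.
#' @param eps deviation \eqn{\epsilon} from \eqn{r^*} (default 0).
#' @param resonance_tol tolerance for the strong-resonance exclusion
#'   \eqn{|\rho^m - 1| >} `resonance_tol`, `m = 1..4`.
#' @return Class `"ricker_holling_ns_linear"`: `eta`, `zeta`, complex `rho`,
#'   `modulus`, `dmod_deps`, logical `resonance_ok[4]`, `eps`.
#' @examples
#' ns_linear_data(ricker_holling(2, 2, 1))   # rho = exp(i pi/3)
#' @export
ns_linear_data <- function(model, eps = 0, resonance_tol = 1e-6) {
  stopifnot(inherits(model, "ricker_holling"))
  a <- model$alpha; g <- model$gamma
  if (a <= g) abort_domain("requires alpha > gamma")
  cf <- p1_lin_coefs(a, g)
  reff <- model$r + eps
  tr <- 2 - cf$cP * reff
  de <- 1 + cf$cq * reff
  disc <- 4 * de - tr^2
  if (disc <= 0)
    abort_domain(paste(
      "multipliers are real (flip/saddle regime):",
      "Neimark-Sacker linear data undefined"))
  eta <- tr / 2
  zeta <- sqrt(disc) / 2
  rho <- complex(real = eta, imaginary = zeta)
  structure(list(
    eta = eta, zeta = zeta, rho = rho,
    modulus = sqrt(de),
    dmod_deps = cf$cq / (2 * sqrt(de)),
    resonance_ok = vapply(1:4, function(m) Mod(rho^m - 1) > resonance_tol,
                          logical(1)),
    eps = eps),
    class = "ricker_holling_ns_linear")
}

#' Taylor coefficients of the shifted map at the interior fixed point
#'
#' Coefficients of the expansion of the map, shifted so that \eqn{p_1} sits
#' at the origin, through third order:
#' \deqn{u' = B_{11}u + B_{12}v + B_{13}u^2 + B_{14}uv + B_{15}u^3 +
#'   B_{16}u^2v + \dots,\quad
#'   v' = B_{21}u + B_{22}v + B_{23}u^2 + B_{24}uv + B_{25}u^3 + B_{26}u^2v
#'   + \dots}
#' The linear coefficients are the Jacobian entries (in particular
#' \eqn{B_{22} = 1} at \eqn{p_1}, since \eqn{\alpha x^*/(1+x^*) = \gamma});
#' the quadratic and cubic ones follow from the derivatives of the Ricker
#' term \eqn{r x e^{1-x}} and the Holling term \eqn{\alpha x y/(1+x)}.
#'
#' @param model a [ricker_holling()] model with `alpha > gamma`.
#' @return Named list `B11..B26` plus `xstar`, `ystar`.
#' @export
ns_taylor_coeffs <- function(model) {
  stopifnot(inherits(model, "ricker_holling"))
  if (model$alpha <= model$gamma) abort_domain("requires alpha > gamma")
  st <- interior_state(model)
  taylor_B(model$r, model$alpha, model$gamma, st[1], st[2])
}

## Shared by the NS and flip expansions (the flip list adds B17, B18).
taylor_B <- function(r, a, g, xs, ys) {
  ee <- exp(1 - xs)
  ip <- 1 / (1 + xs)
  list(xstar = xs, ystar = ys,
       B11 = 1 + r * ee * (1 - xs) - a * ys * ip^2,
       B12 = -a * xs * ip,
       B13 = (r * ee * (xs - 2) + 2 * a * ys * ip^3) / 2,
       B14 = -a * ip^2,
       B15 = (r * ee * (3 - xs) - 6 * a * ys * ip^4) / 6,
       B16 = a * ip^3,
       B21 = a * ys * ip^2,
       B22 = 1 - g + a * xs * ip,
       B23 = -a * ys * ip^3,
       B24 = a * ip^2,
       B25 = a * ys * ip^4,
       B26 = -a * ip^3)
}

## Coefficients of the nonlinear parts (Psi, Phi) after the real-eigenbasis
## transformation (u,v) = T (X,Y) with T = (B12, 0; eta - B11, -zeta):
##   Psi = A11 X^3 + A12 X Y + A13 X^2 + A14 X^2 Y
##   Phi = A21 X^3 + A22 X Y + A23 X^2 + A24 X^2 Y
## Obtained by substituting u = B12 X, v = (eta - B11) X - zeta Y into the
## quadratic/cubic terms and applying T^{-1}.
ns_A_from_B <- function(B, eta, zeta) {
  d <- eta - B$B11
  b <- B$B12
  list(
    A11 = b * (b * B$B15 + B$B16 * d),
    A12 = -zeta * B$B14,
    A13 = b * B$B13 + B$B14 * d,
    A14 = -zeta * b * B$B16,
    A21 = b * (-B$B25 * b^2 + b * (B$B15 - B$B26) * d + B$B16 * d^2) / zeta,
    A22 = b * B$B24 - B$B14 * d,
    A23 = (-B$B23 * b^2 + b * (B$B13 - B$B24) * d + B$B14 * d^2) / zeta,
    A24 = b * (b * B$B26 - B$B16 * d))
}

## delta coefficients and first Lyapunov coefficient chi from the A's.
## delta21 follows the general definition
##   (1/16)[Psi_XXX + Psi_XYY + Phi_XXY + Phi_YYY
##          + i (Phi_XXX + Phi_XYY - Psi_XXY - Psi_YYY)]
## which reduces (Psi_XYY = Psi_YYY = Phi_XYY = Phi_YYY = 0 here) to
## (3 A11 + A24 + i (3 A21 - A14))/8; the A14 in the imaginary part is what
## makes chi invariant under the conjugate choice of rho.
ns_delta_chi <- function(A, rho) {
  d11 <- (A$A13 + 1i * A$A23) / 2
  d20 <- (A$A13 + A$A22 + 1i * (A$A23 - A$A12)) / 4
  d02 <- (A$A13 + A$A22 + 1i * (A$A23 + A$A12)) / 4
  d21 <- (3 * A$A11 + A$A24 + 1i * (3 * A$A21 - A$A14)) / 8
  chi <- -Re(((1 - 2 * Conj(rho)) * Conj(rho)^2 / (1 - rho)) * d11 * d20) -
    0.5 * Mod(d11)^2 - Mod(d02)^2 + Re(Conj(rho) * d21)
  list(delta11 = d11, delta20 = d20, delta02 = d02, delta21 = d21, chi = chi)
}

#' Neimark-Sacker normal form and first Lyapunov coefficient
#'
#' Computes, at \eqn{\epsilon = 0} (i.e. at the supplied `model$r`), the
#' Taylor coefficients `B` of the shifted map, the transformed nonlinear
#' coefficients `A`, the complex normal-form quantities
#' \eqn{\delta_{11}, \delta_{20}, \delta_{02}, \delta_{21}}, and the first
#' Lyapunov coefficient
#' \deqn{\chi = -\mathrm{Re}\!\left[\frac{(1-2\bar\rho)\bar\rho^2}{1-\rho}
#'   \delta_{11}\delta_{20}\right] - \tfrac12|\delta_{11}|^2 -
#'   |\delta_{02}|^2 + \mathrm{Re}(\bar\rho\,\delta_{21}).}
#' \eqn{\chi < 0} indicates an attracting invariant closed curve
#' (supercritical), \eqn{\chi > 0} a repelling one.  Because
#' \eqn{\det - 1 \propto r} for this map, an isolated Neimark-Sacker
#' crossing in `r` does not exist off the degenerate surface, so \eqn{\chi}
#' is exposed at user-supplied \eqn{(\alpha,\gamma,r)} with
#' \eqn{|\rho| = \sqrt{\det}} as computed (not forced to 1).
#'
#' @inheritParams ns_linear_data
#' @return Class `"ricker_holling_ns"`: `linear` (the
#'   [ns_linear_data()] result), `B`, `A`, `delta` (complex list), `chi`,
#'   and a human-readable `verdict`.
#' @examples
#' nf <- ns_normal_form(ricker_holling(2, 0.847723, 0.3))
#' nf$chi
#' @export
ns_normal_form <- function(model, resonance_tol = 1e-6) {
  lin <- ns_linear_data(model, eps = 0, resonance_tol = resonance_tol)
  if (!all(lin$resonance_ok)) {
    m <- which(!lin$resonance_ok)[1]
    abort_domain(sprintf(
      "strong resonance: |rho^%d - 1| <= %g; normal form invalid", m,
      resonance_tol))
  }
  B <- ns_taylor_coeffs(model)
  A <- ns_A_from_B(B, lin$eta, lin$zeta)
  dc <- ns_delta_chi(A, lin$rho)
  verdict <- if (dc$chi < 0) {
    "chi < 0: attracting (supercritical) invariant closed curve"
  } else if (dc$chi > 0) {
    "chi > 0: repelling (subcritical) invariant closed curve"
  } else "chi = 0: degenerate"
  structure(list(linear = lin, B = B, A = A,
                 delta = dc[c("delta11", "delta20", "delta02", "delta21")],
                 chi = dc$chi, verdict = verdict),
            class = "ricker_holling_ns")
}

#' @export
print.ricker_holling_ns <- function(x, ...) {
  cat("Neimark-Sacker normal form at the interior fixed point\n")
  cat(sprintf("  rho = %s (|rho| = %.7g), d|rho|/deps = %.7g\n",
              format(x$linear$rho, digits = 7), x$linear$modulus,
              x$linear$dmod_deps))
  cat(sprintf("  chi = %.7g\n  %s\n", x$chi, x$verdict))
  invisible(x)
}
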