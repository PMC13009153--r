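#' Construct a Ricker-Holling predator-prey map
#'
#' Builds the model object for the discrete-time map
#' \deqn{x_{n+1} = x_n + r x_n e^{1-x_n} - \frac{\alpha x_n y_n}{1+x_n},
#'       \qquad
#'       y_{n+1} = y_n + \frac{\alpha x_n y_n}{1+x_n} - \gamma y_n.}
#' All three parameters are dimensionless and strictly positive: `r` is the
#' prey intrinsic growth rate, `alpha` the predation/conversion rate of the
#' Holling type II response, and `gamma` the predator mortality.  An interior
#' (coexistence) fixed point exists iff `alpha > gamma`.
#'
#' @param r prey intrinsic growth rate, `> 0`.
#' @param alpha predation/conversion rate, `> 0`.
#' @param gamma predator mortality rate, `> 0`.
#' @return An object of class `"ricker_holling"`: a list with elements
#'   `r`, `alpha`, `gamma`.
#' @examples
#' m <- ricker_holling(r = 3.598768, alpha = 2, gamma = 1)
#' fixed_points(m)
#' @seealso [fixed_points()], [map_step()], [jacobian_eval()]
#' @export
ricker_holling <- function(r, alpha, gamma) {
  for (nm in c("r", "alpha", "gamma")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0)
      abort_domain(sprintf("parameter '%s' must be a single positive finite number", nm))
  }
  structure(list(r = r, alpha = alpha, gamma = gamma), class = "ricker_holling")
}

#' @export
coef.ricker_holling <- function(object, ...) {
  c(r = object$r, alpha = object$alpha, gamma = object$gamma)
}

#' @export
print.ricker_holling <- function(x, ...) {
  cat("Discrete Ricker-Holling predator-prey map\n")
  cat("  x' = x + r x e^(1-x) - a x y/(1+x)\n")
  cat("  y' = y + a x y/(1+x) - g y\n")
  cat(sprintf("  r = %.6g, alpha = %.6g, gamma = %.6g\n", x$r, x$alpha, x$gamma))
  fps <- fixed_points(x)
  for (fp in fps)
    cat(sprintf("  %s fixed point: (%.7g, %.7g)\n", fp$kind, fp$state[1], fp$state[2]))
  if (x$alpha <= x$gamma)
    cat("  (no interior fixed point: alpha <= gamma)\n")
  invisible(x)
}

## shared closed-form helpers ------------------------------------------------

## e^{(alpha-2 gamma)/(alpha-gamma)}; every closed form at the interior point
## carries this factor.
exp_factor <- function(alpha, gamma) exp((alpha - 2 * gamma) / (alpha - gamma))

## trace(J(p1)) = 2 - cP*r ; det(J(p1)) = 1 + cq*r  (linear in r).
p1_lin_coefs <- function(alpha, gamma) {
  E <- exp_factor(alpha, gamma)
  list(
    cP = gamma^2 * E / (alpha * (alpha - gamma)),
    cq = gamma * (gamma^2 - gamma + alpha^2 - 2 * alpha * gamma) * E /
      (alpha * (alpha - gamma))
  )
}

p1_trace_det <- function(r, alpha, gamma) {
  cf <- p1_lin_coefs(alpha, gamma)
  c(trace = 2 - cf$cP * r, det = 1 + cf$cq * r)
}

#' Advance the map one step
#'
#' Applies the map once.  The raw map is iterated over the reals with no
#' clamping: states that leave the non-negative quadrant are mathematically
#' valid (and are flagged, not altered, by the simulation tools).
#'
#' @param model a [ricker_holling()] model.
#' @param state numeric vector `c(x, y)`, or an n-by-2 matrix of states.
#' @return A vector or matrix of the same shape holding the mapped state(s).
#' @examples
#' m <- ricker_holling(1, 1, 0.5)
#' map_step(m, c(0.33, 0.64))
#' @export
map_step <- function(model, state) {
  stopifnot(inherits(model, "ricker_holling"))
  mat <- is.matrix(state)
  s <- if (mat) state else matrix(state, ncol = 2)
  if (ncol(s) != 2L) abort_domain("state must have two components (x, y)")
  x <- s[, 1]; y <- s[, 2]
  H <- model$alpha * x * y / (1 + x)
  out <- cbind(x + model$r * x * exp(1 - x) - H,
               y + H - model$gamma * y)
  if (mat) {
    colnames(out) <- c("x", "y")
    out
  } else c(x = out[1, 1], y = out[1, 2])
}

#' Fixed points of the map
#'
#' The trivial (extinction) point \eqn{p_0 = (0,0)} always exists.  The
#' interior (coexistence) point
#' \eqn{p_1 = (\gamma/(\alpha-\gamma),\;
#'   r/(\alpha-\gamma)\, e^{(\alpha-2\gamma)/(\alpha-\gamma)})}
#' exists iff \eqn{\alpha > \gamma}.
#'
#' @param model a [ricker_holling()] model.
#' @return A list of fixed points, each of class `"ricker_holling_fp"` with
#'   elements `state` (named numeric) and `kind` (`"trivial"` or
#'   `"interior"`).
#' @examples
#' fixed_points(ricker_holling(2, 0.5, 0.3))
#' @export
fixed_points <- function(model) {
  stopifnot(inherits(model, "ricker_holling"))
  out <- list(new_fp(c(0, 0), "trivial"))
  if (model$alpha > model$gamma)
    out <- c(out, list(new_fp(interior_state(model), "interior")))
  out
}

interior_state <- function(model) {
  a <- model$alpha; g <- model$gamma
  c(g / (a - g), model$r / (a - g) * exp_factor(a, g))
}

new_fp <- function(state, kind) {
  structure(list(state = c(x = state[[1]], y = state[[2]]), kind = kind),
            class = "ricker_holling_fp")
}

#' @export
print.ricker_holling_fp <- function(x, ...) {
  cat(sprintf("%s fixed point (%.7g, %.7g)\n", x$kind, x$state[1], x$state[2]))
  invisible(x)
}

#' Interior fixed point
#'
#' @param model a [ricker_holling()] model with `alpha > gamma`.
#' @return The interior fixed point, class `"ricker_holling_fp"`.
#' @export
interior_fixed_point <- function(model) {
  stopifnot(inherits(model, "ricker_holling"))
  if (model$alpha <= model$gamma)
    abort_domain("no interior fixed point: requires alpha > gamma")
  new_fp(interior_state(model), "interior")
}

## ordered multipliers of rho^2 - trace*rho + det ----------------------------
## rho1 has the larger modulus; complex pairs are conjugate with the
## positive-imaginary root first.
char_multipliers <- function(trace, det) {
  disc <- trace^2 - 4 * det
  if (disc >= 0) {
    s <- sqrt(disc)
    roots <- c((trace + s) / 2, (trace - s) / 2)
    roots <- roots[order(-abs(roots))]
    complex(real = roots, imaginary = c(0, 0))
  } else {
    im <- sqrt(-disc) / 2
    complex(real = c(trace, trace) / 2, imaginary = c(im, -im))
  }
}

#' Jacobian of the map at a state
#'
#' Analytic linearization
#' \deqn{J(x,y) = \begin{pmatrix}
#'   1 + r e^{1-x}(1-x) - \alpha y/(1+x)^2 & -\alpha x/(1+x) \\
#'   \alpha y/(1+x)^2 & 1-\gamma+\alpha x/(1+x) \end{pmatrix},}
#' with trace, determinant and the multipliers (eigenvalues)
#' \eqn{\rho_{1,2}} of the characteristic quadratic
#' \eqn{R(\rho) = \rho^2 - \mathrm{trace}\,\rho + \det}.  At the interior
#' fixed point \eqn{\alpha x^*/(1+x^*) = \gamma}, so the lower-right entry
#' equals 1 exactly.
#'
#' @param model a [ricker_holling()] model.
#' @param state numeric `c(x, y)` with `x != -1`.
#' @return An object of class `"ricker_holling_jac"`: entries `j11, j12,
#'   j21, j22`, `trace`, `det`, and complex `multipliers` (largest modulus
#'   first; conjugate pairs with positive imaginary part first).
#' @examples
#' m <- ricker_holling(3.598768, 2, 1)
#' jacobian_eval(m, interior_fixed_point(m)$state)
#' @export
jacobian_eval <- function(model, state) {
  stopifnot(inherits(model, "ricker_holling"))
  if (inherits(state, "ricker_holling_fp")) state <- state$state
  x <- state[[1]]; y <- state[[2]]
  if (!is.finite(x) || !is.finite(y))
    abort_domain("state must be finite")
  if (x == -1)
    abort_domain("Jacobian undefined at x = -1 (pole of the Holling term)")
  ip <- 1 / (1 + x)
  j11 <- 1 + model$r * exp(1 - x) * (1 - x) - model$alpha * y * ip^2
  j12 <- -model$alpha * x * ip
  j21 <- model$alpha * y * ip^2
  j22 <- 1 - model$gamma + model$alpha * x * ip
  tr <- j11 + j22
  de <- j11 * j22 - j12 * j21
  structure(list(j11 = j11, j12 = j12, j21 = j21, j22 = j22,
                 trace = tr, det = de,
                 multipliers = char_multipliers(tr, de)),
            class = "ricker_holling_jac")
}

#' @export
print.ricker_holling_jac <- function(x, ...) {
  m <- matrix(c(x$j11, x$j12, x$j21, x$j22), 2, 2, byrow = TRUE)
  cat("Jacobian:\n"); print(m)
  cat(sprintf("trace = %.7g, det = %.7g\n", x$trace, x$det))
  cat("multipliers:", format(x$multipliers, digits = 7), "\n")
  invisible(x)
}
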