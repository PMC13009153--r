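#' Classify a (trace, det) pair by jury conditions
#'
#' For the characteristic quadratic \eqn{R(\rho)=\rho^2-\mathrm{trace}\,\rho
#' +\det}, the jury conditions locate the roots relative to the unit circle:
#' both inside iff \eqn{R(1)>0}, \eqn{R(-1)>0} and \eqn{\det<1}.  The
#' classification is computed from the multiplier moduli, which is equivalent
#' but behaves transparently near boundaries: any modulus within `tol` of 1
#' yields `"non_hyperbolic"` regardless of the other multiplier.
#'
#' @param trace,det trace and determinant of the 2x2 linearization.
#' @param tol unit-circle tolerance, in `(0, 0.1)`.
#' @return One of `"LAS"` (locally asymptotically stable), `"source"`,
#'   `"saddle"`, `"non_hyperbolic"`.
#' @examples
#' jury_classify(0, 0.5)   # complex pair inside the unit circle
#' jury_classify(0, 1)     # unit-modulus complex pair
#' @export
jury_classify <- function(trace, det, tol = 1e-9) {
  if (!is_scalar_number(trace) || !is_scalar_number(det))
    abort_domain("trace and det must be finite scalars")
  if (!is_scalar_number(tol) || tol <= 0 || tol >= 0.1)
    abort_domain("tol must lie in (0, 0.1)")
  m <- Mod(char_multipliers(trace, det))
  if (any(abs(m - 1) <= tol)) return("non_hyperbolic")
  if (all(m < 1)) return("LAS")
  if (all(m > 1)) return("source")
  "saddle"
}

## R(1), R(-1) and det for the jury table.
jury_values <- function(trace, det) {
  c(R1 = 1 - trace + det, Rm1 = 1 + trace + det, det = det)
}

#' Stability report for a fixed point
#'
#' Evaluates the Jacobian at the fixed point, the jury values
#' \eqn{R(1)}, \eqn{R(-1)}, \eqn{\det}, and classifies the point from the
#' multiplier moduli.  The trivial point has the diagonal Jacobian with
#' multipliers \eqn{\{1+re,\ 1-\gamma\}}; since \eqn{1+re>1} for every
#' \eqn{r>0} it is a saddle whenever \eqn{0<\gamma<2} (see
#' [origin_printed_condition()] for the commonly quoted -- but inconsistent --
#' sink inequality).
#'
#' @param model a [ricker_holling()] model.
#' @param fp a fixed point from [fixed_points()] / [interior_fixed_point()],
#'   or the string `"trivial"` / `"interior"`.
#' @param tol unit-circle tolerance passed to [jury_classify()].
#' @return Class `"ricker_holling_stability"`: the fixed point, its Jacobian,
#'   `classification`, the `jury` values, `tol` and the character vector
#'   `corrections_applied` documenting where the implementation departs from
#'   commonly printed criteria.
#' @examples
#' classify_fixed_point(ricker_holling(3.5, 0.5, 0.3), "interior")
#' @export
classify_fixed_point <- function(model, fp = "interior", tol = 1e-9) {
  stopifnot(inherits(model, "ricker_holling"))
  if (is.character(fp)) {
    fp <- switch(match.arg(fp, c("interior", "trivial")),
                 interior = interior_fixed_point(model),
                 trivial  = new_fp(c(0, 0), "trivial"))
  }
  jac <- jacobian_eval(model, fp$state)
  corrections <- character()
  if (fp$kind == "trivial") {
    corrections <- c(corrections, paste(
      "trivial point classified from its exact multipliers {1 + r e, 1 - gamma};",
      "the printed sink inequality r e (1 - gamma) < gamma is reported by",
      "origin_printed_condition() but is inconsistent with 1 + r e > 1"))
  }
  structure(list(fixed_point = fp, jac = jac,
                 classification = jury_classify(jac$trace, jac$det, tol),
                 jury = as.list(jury_values(jac$trace, jac$det)),
                 tol = tol, corrections_applied = corrections),
            class = "ricker_holling_stability")
}

#' @export
print.ricker_holling_stability <- function(x, ...) {
  cat(sprintf("%s fixed point (%.7g, %.7g): %s\n",
              x$fixed_point$kind, x$fixed_point$state[1], x$fixed_point$state[2],
              x$classification))
  cat(sprintf("  multipliers: %s\n",
              paste(format(x$jac$multipliers, digits = 7), collapse = ", ")))
  cat(sprintf("  jury: R(1) = %.6g, R(-1) = %.6g, det = %.6g\n",
              x$jury$R1, x$jury$Rm1, x$jury$det))
  invisible(x)
}

#' @export
summary.ricker_holling <- function(object, tol = 1e-9, ...) {
  reps <- lapply(fixed_points(object), classify_fixed_point,
                 model = object, tol = tol)
  structure(list(model = object, reports = reps),
            class = "summary.ricker_holling")
}

#' @export
print.summary.ricker_holling <- function(x, ...) {
  print(x$model)
  cat("\nStability:\n")
  for (rep in x$reports) print(rep)
  invisible(x)
}

#' Closed-form jury expressions at the interior fixed point
#'
#' At \eqn{p_1} the trace and determinant are linear in `r`:
#' \eqn{\mathrm{trace} = 2 - c_P r}, \eqn{\det = 1 + c_q r} with
#' \eqn{c_P = \gamma^2 E/(\alpha(\alpha-\gamma))},
#' \eqn{c_q = \gamma(\gamma^2-\gamma+\alpha^2-2\alpha\gamma)E/
#' (\alpha(\alpha-\gamma))} and
#' \eqn{E = e^{(\alpha-2\gamma)/(\alpha-\gamma)}}.
#' The three returned scalars are the jury expressions
#' \eqn{R(1)}, \eqn{R(-1)} and \eqn{\det-1}; the sign pattern
#' \eqn{(+,+,-)} is equivalent to local asymptotic stability.  Note
#' \eqn{R(1) = rE\gamma(\alpha-\gamma)^2/(\alpha(\alpha-\gamma)) > 0}
#' automatically for \eqn{\alpha>\gamma}, which is why the flip boundary is
#' \eqn{R(-1)=0} and never \eqn{R(1)=0}.
#'
#' @param model a [ricker_holling()] model with `alpha > gamma`.
#' @return Named numeric vector `c(R1, Rm1, det_minus_1)`.
#' @examples
#' stability_conditions(ricker_holling(3.5, 0.5, 0.3))
#' @export
stability_conditions <- function(model) {
  stopifnot(inherits(model, "ricker_holling"))
  a <- model$alpha; g <- model$gamma; r <- model$r
  if (a <= g) abort_domain("interior conditions require alpha > gamma")
  E <- exp_factor(a, g)
  c(R1  = r * E * g * (g^2 + a^2 - 2 * a * g) / (a * (a - g)),
    Rm1 = 4 + r * E * g * (g^2 - 2 * g + a^2 - 2 * a * g) / (a * (a - g)),
    det_minus_1 = r * E * g * (g^2 - g + a^2 - 2 * a * g) / (a * (a - g)))
}

#' Critical growth rate of the flip (period-doubling) bifurcation
#'
#' Solves \eqn{R(-1) = 1 + \mathrm{trace} + \det = 0} at the interior fixed
#' point in closed form:
#' \deqn{r_c = \frac{-4\,\alpha(\alpha-\gamma)\,
#'   e^{-(\alpha-2\gamma)/(\alpha-\gamma)}}
#'   {\gamma(\gamma^2-2\gamma+\alpha^2-2\alpha\gamma)}.}
#' A positive root exists iff the denominator coefficient is negative.
#' Note the root only marks a *generic* flip when the other multiplier is
#' off the unit circle; [flip_setup()] checks that (e.g. at
#' `alpha = 2, gamma = 1` the root r = 8 is a degenerate 1:2 resonance with
#' both multipliers at -1).
#'
#' @param alpha,gamma model parameters with `alpha > gamma`.
#' @return The critical rate \eqn{r_c > 0}.
#' @examples
#' critical_r_flip(0.5, 0.3)   # 3.925527
#' critical_r_flip(1, 0.5)     # 16/3
#' @export
critical_r_flip <- function(alpha, gamma) {
  if (!is_scalar_number(alpha) || !is_scalar_number(gamma) ||
      alpha <= 0 || gamma <= 0)
    abort_domain("alpha and gamma must be positive finite scalars")
  if (alpha <= gamma) abort_domain("flip analysis requires alpha > gamma")
  cf <- gamma * (gamma^2 - 2 * gamma + alpha^2 - 2 * alpha * gamma) *
    exp_factor(alpha, gamma) / (alpha * (alpha - gamma))
  if (cf >= 0)
    abort_domain(paste(
      "no flip bifurcation in r: R(-1) = 4 + c*r has non-negative slope",
      sprintf("(coefficient %.6g >= 0), so R(-1) > 0 for every r > 0", cf)))
  -4 / cf
}

#' Bifurcation condition residuals at the interior fixed point
#'
#' `flip_condition()` returns the residual \eqn{R(-1) = 1+\mathrm{trace}+\det}
#' whose zero marks flip criticality; `ns_condition()` returns
#' \eqn{\det - 1}, whose zero (with a complex pair, i.e.
#' \eqn{\mathrm{trace}^2 < 4\det}) marks Neimark-Sacker criticality.
#' Because \eqn{\det - 1 = c_q r} is proportional to \eqn{r}, it vanishes at
#' some \eqn{r>0} only on the degenerate parameter surface
#' \eqn{\gamma^2-\gamma+\alpha^2-2\alpha\gamma = 0}, where it vanishes for
#' *every* r (and the radial transversality derivative is 0).
#'
#' @param model a [ricker_holling()] model with `alpha > gamma`.
#' @return Class `"ricker_holling_bifcond"`: `kind`, `residual`,
#'   `side_conditions` (named logicals/values), and for the NS case
#'   `degenerate_surface`, the parameter-only factor
#'   \eqn{\gamma^2-\gamma+\alpha^2-2\alpha\gamma}.
#' @examples
#' ns_condition(ricker_holling(3.5, 0.5, 0.3))
#' ns_condition(ricker_holling(2, 2, 1))     # residual identically 0
#' @export
ns_condition <- function(model) {
  stopifnot(inherits(model, "ricker_holling"))
  a <- model$alpha; g <- model$gamma
  if (a <= g) abort_domain("requires alpha > gamma")
  td <- p1_trace_det(model$r, a, g)
  structure(list(
    kind = "neimark_sacker",
    residual = td[["det"]] - 1,
    side_conditions = list(abs_trace_lt_2 = abs(td[["trace"]]) < 2,
                           complex_pair = td[["trace"]]^2 - 4 * td[["det"]] < 0,
                           trace = td[["trace"]], det = td[["det"]]),
    degenerate_surface = g^2 - g + a^2 - 2 * a * g),
    class = "ricker_holling_bifcond")
}

#' @rdname ns_condition
#' @export
flip_condition <- function(model) {
  stopifnot(inherits(model, "ricker_holling"))
  a <- model$alpha; g <- model$gamma
  if (a <= g) abort_domain("requires alpha > gamma")
  td <- p1_trace_det(model$r, a, g)
  structure(list(
    kind = "flip",
    residual = 1 + td[["trace"]] + td[["det"]],
    side_conditions = list(det_positive = td[["det"]] > 0,
                           trace = td[["trace"]], det = td[["det"]])),
    class = "ricker_holling_bifcond")
}

#' @export
print.ricker_holling_bifcond <- function(x, ...) {
  cat(sprintf("%s condition residual: %.7g\n", x$kind, x$residual))
  invisible(x)
}

#' The printed sink inequality for the extinction point, as printed
#'
#' A commonly quoted criterion claims the origin is a sink when
#' \eqn{r e (1-\gamma) < \gamma}.  The exact multipliers at the origin are
#' \eqn{1 + r e} and \eqn{1-\gamma}; the first exceeds 1 for every
#' \eqn{r > 0}, so the origin is in fact a saddle whenever
#' \eqn{0 < \gamma < 2} and a non-hyperbolic point at \eqn{\gamma = 2}.
#' The function evaluates the printed inequality for transparency; the
#' package never uses it for classification.
#'
#' @param model a [ricker_holling()] model.
#' @return A list with the printed left/right sides, whether the printed
#'   inequality holds, the exact multipliers, and the classification actually
#'   used.
#' @export
origin_printed_condition <- function(model) {
  stopifnot(inherits(model, "ricker_holling"))
  lhs <- model$r * exp(1) * (1 - model$gamma)
  list(printed_lhs = lhs, printed_rhs = model$gamma,
       printed_sink = lhs < model$gamma,
       multipliers = c(1 + model$r * exp(1), 1 - model$gamma),
       classification = classify_fixed_point(model, "trivial")$classification,
       note = "as printed; inconsistent with multiplier 1 + r e > 1")
}
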