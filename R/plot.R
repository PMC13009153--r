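#' Phase portrait of a simulated orbit
#'
#' @param x a `"ricker_holling_orbit"`.
#' @param type plot type (points by default).
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.ricker_holling_orbit <- function(x, type = "p", ...) {
  model <- attr(x, "model")
  plot(x$x, x$y, type = type, pch = 20, cex = 0.4,
       xlab = "prey x", ylab = "predator y",
       main = sprintf("r = %.4g, alpha = %.4g, gamma = %.4g",
                      model$r, model$alpha, model$gamma), ...)
  if (model$alpha > model$gamma) {
    fp <- interior_fixed_point(model)$state
    points(fp[1], fp[2], pch = 3, col = 2, cex = 1.2)
  }
  invisible(x)
}

#' Phase portrait of the model
#'
#' Simulates a default orbit and plots it; the interior fixed point (when it
#' exists) is marked with a cross.
#'
#' @param x a [ricker_holling()] model.
#' @param nsim,transient,x0 passed to [simulate.ricker_holling()].
#' @param ... passed to the orbit plot.
#' @return The simulated orbit, invisibly.
#' @export
plot.ricker_holling <- function(x, nsim = 2000, transient = 500,
                                x0 = c(0.33, 0.64), ...) {
  orb <- simulate(x, nsim = nsim, transient = transient, x0 = x0)
  plot(orb, ...)
  invisible(orb)
}

#' Bifurcation diagram and Lyapunov panel
#'
#' Two stacked panels: attractor samples of the prey coordinate against the
#' swept growth rate, and the maximal Lyapunov exponent with a zero line.
#'
#' @param x a `"ricker_holling_diagram"`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.ricker_holling_diagram <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  long <- as.data.frame(x)
  plot(long$r, long$x, pch = ".", xlab = "r", ylab = "prey x",
       main = sprintf("alpha = %.4g, gamma = %.4g", x$alpha, x$gamma))
  sm <- x$summary
  mle <- ifelse(is.finite(sm$mle), sm$mle, NA)
  plot(sm$r, mle, type = "l", xlab = "r",
       ylab = "max Lyapunov exponent")
  abline(h = 0, lty = 2)
  invisible(x)
}
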