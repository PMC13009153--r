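## Core iteration engine ----------------------------------------------------
## One plain-R loop shared by simulate(), max_lyapunov() and the sweeps.
## Records post-transient states; optionally propagates a tangent vector
## through the analytic Jacobian with per-step renormalization, accumulating
## log norms only after the transient.  Divergence (non-finite state or
## |x|,|y| > bound) is data, not an error.
iterate_map <- function(r, alpha, gamma, x0, n, transient, bound = 1e6,
                        tangent = FALSE, v0 = c(1, 0)) {
  keep <- if (n > 0) matrix(NA_real_, n, 2) else matrix(numeric(0), 0, 2)
  x <- x0[[1]]; y <- x0[[2]]
  admissible <- x >= 0 && y >= 0
  diverged <- NA_integer_
  logsum <- 0; nlog <- 0L
  v1 <- v0[[1]]; v2 <- v0[[2]]
  total <- transient + n
  i <- 0L
  while (i < total) {
    i <- i + 1L
    if (tangent) {
      ex <- exp(1 - x); ip <- 1 / (1 + x)
      j11 <- 1 + r * ex * (1 - x) - alpha * y * ip * ip
      j12 <- -alpha * x * ip
      j21 <- alpha * y * ip * ip
      j22 <- 1 - gamma + alpha * x * ip
      w1 <- j11 * v1 + j12 * v2
      w2 <- j21 * v1 + j22 * v2
      nv <- sqrt(w1 * w1 + w2 * w2)
      if (i > transient) { logsum <- logsum + log(nv); nlog <- nlog + 1L }
      if (nv > 0 && is.finite(nv)) { v1 <- w1 / nv; v2 <- w2 / nv }
    }
    H <- alpha * x * y / (1 + x)
    xn <- x + r * x * exp(1 - x) - H
    yn <- y + H - gamma * y
    x <- xn; y <- yn
    if (!is.finite(x) || !is.finite(y) || abs(x) > bound || abs(y) > bound) {
      diverged <- i
      break
    }
    if (x < 0 || y < 0) admissible <- FALSE
    if (i > transient) keep[i - transient, ] <- c(x, y)
  }
  kept <- if (is.na(diverged)) n else max(0L, i - 1L - transient)
  list(points = keep[seq_len(max(kept, 0L)), , drop = FALSE],
       diverged = diverged, admissible = admissible,
       logsum = logsum, nlog = nlog, last = c(x, y))
}

## Run `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

#' Simulate an orbit of the map
#'
#' Iterates the map from `x0`, discards `transient` steps and returns the
#' next `nsim` states.  Iteration stops early (with a divergence flag) when
#' the state becomes non-finite or leaves `[-bound, bound]^2`; orbits that
#' visit the negative quadrant are flagged as not biologically admissible
#' but are never clamped.
#'
#' @param object a [ricker_holling()] model.
#' @param nsim number of post-transient states to record.
#' @param seed unused (the map is deterministic); accepted for generic
#'   compatibility.
#' @param x0 initial state `c(x, y)`.
#' @param transient number of initial steps to discard.
#' @param bound divergence bound on `|x|`, `|y|`.
#' @param ... ignored.
#' @return A data frame of class `"ricker_holling_orbit"` with columns
#'   `step`, `x`, `y` and attributes `diverged` (`NA` or the 1-based step
#'   index at which the bound was exceeded), `admissible`, `model`, `x0`,
#'   `transient`.
#' @examples
#' m <- ricker_holling(1, 1, 0.5)
#' head(simulate(m, nsim = 5, x0 = c(0.33, 0.64)))
#' @export
simulate.ricker_holling <- function(object, nsim = 1000, seed = NULL,
                                    x0 = c(0.33, 0.64), transient = 0,
                                    bound = 1e6, ...) {
  stopifnot(nsim >= 0, transient >= 0)
  res <- iterate_map(object$r, object$alpha, object$gamma, x0,
                     n = as.integer(nsim), transient = as.integer(transient),
                     bound = bound)
  orbit <- data.frame(step = seq_len(nrow(res$points)) + transient,
                      x = res$points[, 1], y = res$points[, 2])
  structure(orbit,
            diverged = res$diverged, admissible = res$admissible,
            model = object, x0 = x0, transient = transient,
            class = c("ricker_holling_orbit", "data.frame"))
}

orbit_points <- function(orbit) {
  if (inherits(orbit, "ricker_holling_orbit"))
    cbind(orbit$x, orbit$y)
  else as.matrix(orbit)
}

#' Detect the period of a converged orbit
#'
#' Returns the smallest `k <= max_period` such that, over the last `2k`
#' recorded points, `|s[i+k] - s[i]| < tol` in both coordinates; `NA`
#' (aperiodic) when no such `k` exists.  The orbit must hold at least
#' `4 * max_period` points and must not have diverged.
#'
#' @param orbit a `"ricker_holling_orbit"` (or a 2-column matrix of states).
#' @param tol recurrence tolerance per coordinate.
#' @param max_period largest period searched.
#' @return Integer period, or `NA_integer_` for an aperiodic orbit.
#' @examples
#' m <- ricker_holling(4, 0.5, 0.3)
#' detect_period(simulate(m, nsim = 300, transient = 5000))
#' @export
detect_period <- function(orbit, tol = 1e-6, max_period = 64) {
  if (inherits(orbit, "ricker_holling_orbit") &&
      !is.na(attr(orbit, "diverged")))
    abort_domain("cannot detect a period on a diverged orbit")
  pts <- orbit_points(orbit)
  m <- nrow(pts)
  if (m < 4 * max_period)
    abort_domain(sprintf(
      "orbit too short for period detection: %d points, need >= %d",
      m, 4L * max_period))
  for (k in seq_len(max_period)) {
    i <- (m - 2L * k + 1L):(m - k)
    if (max(abs(pts[i + k, ] - pts[i, ])) < tol) return(k)
  }
  NA_integer_
}

#' Maximal Lyapunov exponent by tangent-vector propagation
#'
#' Propagates a unit tangent vector through the analytic Jacobian along the
#' orbit, renormalizing at every step; the exponent is the average of the
#' log stretch factors over the `n` post-transient steps (the tangent runs
#' through the transient too, but those logs are not accumulated).  The
#' initial tangent direction is drawn from the RNG under `seed`; the
#' estimate is invariant to it up to the quoted reproducibility.
#'
#' @param model a [ricker_holling()] model.
#' @param x0 initial state.
#' @param n number of accumulation steps (`>= 1000`).
#' @param transient discarded steps.
#' @param seed integer seed for the initial tangent direction.
#' @param bound divergence bound.
#' @return Class `"ricker_holling_mle"`: `mle` (nats per iteration; `Inf`
#'   sentinel when the orbit diverges), `n_steps`, `transient`, `seed`,
#'   `diverged`.
#' @examples
#' max_lyapunov(ricker_holling(3.5, 0.5, 0.3), n = 2000)
#' @export
max_lyapunov <- function(model, x0 = c(0.33, 0.64), n = 1e5,
                         transient = 1e3, seed = 0, bound = 1e6) {
  stopifnot(inherits(model, "ricker_holling"))
  if (n < 1e3) abort_domain("max_lyapunov requires n >= 1000")
  theta <- with_seed(seed, runif(1, 0, 2 * pi))
  res <- iterate_map(model$r, model$alpha, model$gamma, x0,
                     n = as.integer(n), transient = as.integer(transient),
                     bound = bound, tangent = TRUE,
                     v0 = c(cos(theta), sin(theta)))
  mle <- if (!is.na(res$diverged)) Inf else res$logsum / res$nlog
  structure(list(mle = mle, n_steps = n, transient = transient, seed = seed,
                 diverged = res$diverged),
            class = "ricker_holling_mle")
}

#' @export
print.ricker_holling_mle <- function(x, ...) {
  if (is.finite(x$mle))
    cat(sprintf("maximal Lyapunov exponent: %.6g nats/iteration (n = %g)\n",
                x$mle, x$n_steps))
  else
    cat(sprintf("orbit diverged at step %d; MLE reported as +Inf\n",
                x$diverged))
  invisible(x)
}
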