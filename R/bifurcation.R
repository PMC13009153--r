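#' Bifurcation-diagram sweep in the growth rate r
#'
#' For each `r` on a uniform grid, simulates the map, samples the
#' post-transient attractor, detects the period and estimates the maximal
#' Lyapunov exponent along the same orbit.  With `warm_start = TRUE`
#' (default) each grid point starts from the previous point's final state,
#' following the stable branch as a continuation would; with
#' `warm_start = FALSE` every grid point restarts from `x0`.
#'
#' @param alpha,gamma fixed model parameters.
#' @param r_min,r_max sweep range (`r_min < r_max`).
#' @param n_r number of grid points (default 600 per unit of `r`).
#' @param x0 initial state (also the restart state after a divergent row).
#' @param transient discarded steps per row.
#' @param n_keep attractor samples recorded per row.
#' @param warm_start logical; continue from the previous row's final state.
#' @param period_tol,max_period passed to [detect_period()].
#' @param mle_steps tangent-accumulation steps per row.
#' @param bound divergence bound.
#' @param seed seed for the initial tangent direction (shared across rows).
#' @return Class `"ricker_holling_diagram"`: `summary` data frame
#'   (`r`, `period`, `mle`, `diverged`, `admissible`), `samples` (list of
#'   `n_keep`-by-2 matrices), the parameters and settings.
#'   `as.data.frame()` flattens to long format (`r`, `sample_index`, `x`,
#'   `y`, `period`, `mle`).
#' @examples
#' d <- bifurcation_sweep(0.5, 0.3, 3.8, 4.1, n_r = 13, transient = 2000)
#' d$summary
#' @export
bifurcation_sweep <- function(alpha, gamma, r_min, r_max,
                              n_r = NULL, x0 = c(0.33, 0.64),
                              transient = 1000, n_keep = 200,
                              warm_start = TRUE,
                              period_tol = 1e-6, max_period = 64,
                              mle_steps = 2000, bound = 1e6, seed = 0) {
  if (!is_scalar_number(r_min) || !is_scalar_number(r_max) || r_min >= r_max)
    abort_domain("need r_min < r_max")
  if (is.null(n_r)) n_r <- max(2L, ceiling(600 * (r_max - r_min)))
  if (n_r < 2) abort_domain("n_r must be >= 2")
  grid <- seq(r_min, r_max, length.out = n_r)
  theta <- with_seed(seed, runif(1, 0, 2 * pi))
  v0 <- c(cos(theta), sin(theta))
  n_post <- max(n_keep, 4L * max_period, mle_steps)
  samples <- vector("list", n_r)
  period <- integer(n_r); mle <- numeric(n_r)
  diverged <- logical(n_r); admissible <- logical(n_r)
  start <- x0
  for (j in seq_len(n_r)) {
    res <- iterate_map(grid[j], alpha, gamma, start,
                       n = n_post, transient = as.integer(transient),
                       bound = bound, tangent = TRUE, v0 = v0)
    if (!is.na(res$diverged)) {
      diverged[j] <- TRUE
      admissible[j] <- res$admissible
      period[j] <- NA_integer_
      mle[j] <- Inf
      samples[[j]] <- matrix(numeric(0), 0, 2)
      start <- x0
      next
    }
    pts <- res$points
    samples[[j]] <- pts[(n_post - n_keep + 1):n_post, , drop = FALSE]
    period[j] <- detect_period(pts, tol = period_tol, max_period = max_period)
    mle[j] <- res$logsum / res$nlog
    admissible[j] <- res$admissible
    start <- if (warm_start) res$last else x0
  }
  structure(list(
    alpha = alpha, gamma = gamma,
    summary = data.frame(r = grid, period = period, mle = mle,
                         diverged = diverged, admissible = admissible),
    samples = samples,
    settings = list(x0 = x0, transient = transient, n_keep = n_keep,
                    warm_start = warm_start, period_tol = period_tol,
                    max_period = max_period, mle_steps = mle_steps,
                    bound = bound, seed = seed)),
    class = "ricker_holling_diagram")
}

#' @export
as.data.frame.ricker_holling_diagram <- function(x, ...) {
  rows <- lapply(seq_along(x$samples), function(j) {
    s <- x$samples[[j]]
    if (nrow(s) == 0)
      return(data.frame(r = x$summary$r[j], sample_index = NA_integer_,
                        x = NA_real_, y = NA_real_,
                        period = x$summary$period[j], mle = x$summary$mle[j]))
    data.frame(r = x$summary$r[j], sample_index = seq_len(nrow(s)),
               x = s[, 1], y = s[, 2],
               period = x$summary$period[j], mle = x$summary$mle[j])
  })
  do.call(rbind, rows)
}

#' @export
print.ricker_holling_diagram <- function(x, ...) {
  cat(sprintf(
    "Bifurcation diagram: alpha = %.6g, gamma = %.6g, r in [%.6g, %.6g] (%d rows)\n",
    x$alpha, x$gamma, min(x$summary$r), max(x$summary$r), nrow(x$summary)))
  per <- x$summary$period
  cat(sprintf("  periods detected: %s; aperiodic rows: %d; divergent rows: %d\n",
              paste(sort(unique(per[!is.na(per)])), collapse = ", "),
              sum(is.na(per) & !x$summary$diverged), sum(x$summary$diverged)))
  invisible(x)
}

#' Locate flip criticality numerically
#'
#' Root of \eqn{R(-1) = 1 + \mathrm{trace} + \det} at the interior fixed
#' point as a function of `r`, by bisection ([stats::uniroot]) on the given
#' bracket.  Serves as an independent numerical cross-check of
#' [critical_r_flip()]; the two agree to `tol` wherever both are defined.
#'
#' @param alpha,gamma model parameters with `alpha > gamma`.
#' @param bracket numeric `c(r_lo, r_hi)` with a sign change of the
#'   residual.
#' @param tol root tolerance.
#' @return The critical rate within the bracket.
#' @examples
#' locate_flip_numeric(0.5, 0.3, c(3, 5))
#' @export
locate_flip_numeric <- function(alpha, gamma, bracket, tol = 1e-8) {
  if (alpha <= gamma) abort_domain("requires alpha > gamma")
  f <- function(r) {
    m <- ricker_holling(r, alpha, gamma)
    j <- jacobian_eval(m, interior_fixed_point(m)$state)
    1 + j$trace + j$det
  }
  lo <- f(bracket[1]); hi <- f(bracket[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
    abort_domain(sprintf(
      "no sign change of R(-1) on the bracket [%g, %g] (values %.4g, %.4g)",
      bracket[1], bracket[2], lo, hi))
  uniroot(f, interval = bracket, tol = tol / 10)$root
}

#' Detect a period-doubling cascade in a diagram
#'
#' Walks the sorted rows and records the first `r` at which the detected
#' period is exactly double the current one (1 -> 2 -> 4 -> ...); the walk
#' stops when detection fails (aperiodic/chaotic rows) after at least one
#' detected row.
#'
#' @param diagram a [bifurcation_sweep()] result.
#' @return A data frame with columns `r_onset`, `period` (possibly empty).
#' @export
cascade_detect <- function(diagram) {
  stopifnot(inherits(diagram, "ricker_holling_diagram"))
  per <- diagram$summary$period
  r <- diagram$summary$r
  onsets <- data.frame(r_onset = numeric(0), period = integer(0))
  cur <- NA_integer_
  for (j in seq_along(per)) {
    p <- per[j]
    if (is.na(p)) {
      ## detection failure ends the walk once the cascade has started;
      ## aperiodic rows before the first doubling (slow transients near the
      ## onset) are skipped
      if (nrow(onsets) > 0) break
      next
    }
    if (is.na(cur)) { cur <- p; next }
    if (p == 2L * cur) {
      onsets <- rbind(onsets, data.frame(r_onset = r[j], period = p))
      cur <- p
    }
  }
  onsets
}
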