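#' Packaged study scenarios
#'
#' The three parameterizations used throughout the numerical study:
#' \describe{
#'   \item{case1}{`alpha = 1, gamma = 0.5`, initial state `(0.33, 0.64)`;
#'     the interior flip sits at `r = 16/3` and a full period-doubling
#'     cascade to chaos unfolds on `r` in roughly `(5.33, 5.64)`.}
#'   \item{case2}{`alpha = 2, gamma = 1`, representative `r = 3.598768`
#'     (interior point `(1, 3.598768)`); the parameters lie on the
#'     degenerate surface `det(J(p1)) = 1`, so orbits near the interior
#'     point wind on invariant closed curves for every `r` with a complex
#'     pair.}
#'   \item{case3}{`alpha = 0.5, gamma = 0.3`, sweep range `3 < r < 6`;
#'     flip at `r ~ 3.9255` followed by a stable period-2 cycle up to a
#'     boundary crisis near `r ~ 5.755`.}
#' }
#'
#' @param name one of `"case1"`, `"case2"`, `"case3"`.
#' @return A list with `name`, `alpha`, `gamma`, `r` (representative rate),
#'   `r_range` (sweep range), `x0`.
#' @examples
#' rickerpp_scenario("case3")
#' @export
rickerpp_scenario <- function(name = c("case1", "case2", "case3")) {
  name <- match.arg(name)
  switch(name,
    case1 = list(name = "case1", alpha = 1, gamma = 0.5, r = 1,
                 r_range = c(0.1, 6), x0 = c(0.33, 0.64)),
    case2 = list(name = "case2", alpha = 2, gamma = 1, r = 3.598768,
                 r_range = c(0.3, 4), x0 = c(0.33, 0.64)),
    case3 = list(name = "case3", alpha = 0.5, gamma = 0.3, r = 3.5,
                 r_range = c(3, 6), x0 = c(0.33, 0.64)))
}

scenario_model <- function(sc, r = NULL) {
  ricker_holling(if (is.null(r)) sc$r else r, sc$alpha, sc$gamma)
}
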