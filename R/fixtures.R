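# Random admissible parameter draws and closed-form test problems for
# property suites.  All randomness is local: the generator saves and
# restores any global RNG state, and identical seeds give identical draws.

default_draw_ranges <- function() {
  # ranged parameters use their tabulated intervals; point-valued ones are
  # jittered +/- 20%, which keeps every rate nonnegative and every
  # saturation/decay constant strictly positive
  fixed <- unlist(model_parameters()[c("u1", "u2", "u3", "s1", "s2", "s3",
                                       "s4", "r1", "r2", "beta1", "omega",
                                       "beta2", "beta3", "beta4", "d1",
                                       "d2", "d3", "vartheta", "b")])
  fixed[c("u1", "u2", "u3")] <- c(0.2, 0.4, 0.5)
  rg <- lapply(fixed, function(v) c(0.8 * v, 1.2 * v))
  c(list(g1 = c(0.1, 0.9), g2 = c(0.2, 0.9), g3 = c(0.2, 0.9),
         g4 = c(0.1, 0.9), delta = c(0.15, 0.60)), rg)
}

#' Draw random admissible parameter sets
#'
#' Uniform, seed-reproducible draws: the five ranged parameters are drawn
#' from their tabulated intervals, every point-valued parameter from a
#' +/- 20% band around its tabulated value (doses around the baseline
#' triple 0.2/0.4/0.5).  Every draw satisfies the [model_parameters()]
#' invariants.  The global RNG state is left untouched.
#'
#' @param n Number of draws (>= 0).
#' @param seed Integer seed; same seed, same draws.
#' @param ranges Named list of `c(lo, hi)` intervals overriding the
#'   defaults for any subset of parameters.
#' @return List of `n` `"crc_params"` objects.
#' @examples
#' draws <- draw_parameters(3, seed = 1)
#' draws[[1]]$g1
#' @export
draw_parameters <- function(n, seed, ranges = list()) {
  stopifnot(n >= 0, length(seed) == 1L, is.finite(seed))
  rg <- modifyList(default_draw_ranges(), ranges)
  bad <- vapply(rg, function(r) length(r) != 2L || !all(is.finite(r)) ||
                  r[1] > r[2] || r[1] < 0, TRUE)
  if (any(bad))
    stop("malformed ranges for: ", paste(names(rg)[bad], collapse = ", "))
  if (n == 0L) return(list())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    vals <- lapply(rg, function(r) runif(1, r[1], r[2]))
    suppressWarnings(do.call(model_parameters, vals))
  })
}

#' Linear Caputo decay test problem with closed-form solution
#'
#' Bundles the scalar field of \eqn{D^\alpha y = -\lambda y} with its exact
#' solution \eqn{y(t) = y_0 E_\alpha(-\lambda t^\alpha)} for solver tests.
#'
#' @param alpha Fractional order in (0, 1].
#' @param rate Decay rate \eqn{\lambda \ge 0}.
#' @param y0 Initial value.
#' @return List with `field` (function of `y`), `y0`, `alpha`, `rate` and
#'   `exact` (vectorized function of `t`).
#' @examples
#' pb <- linear_test_problem(0.9, 1, 1)
#' pb$exact(1)    # mittag_leffler(0.9, -1)
#' @export
linear_test_problem <- function(alpha, rate, y0) {
  check_alpha_sigma(alpha, 1)
  stopifnot(rate >= 0, is.finite(y0))
  list(field = function(y) -rate * y,
       y0 = y0, alpha = alpha, rate = rate,
       exact = function(t) y0 * mittag_leffler(alpha, -rate * t^alpha))
}
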