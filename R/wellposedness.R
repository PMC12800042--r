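# Existence/uniqueness diagnostics.
#
# The five rate kernels are Lipschitz on any box ||T|| < b1, ..., ||P|| < b5,
# with constants that are explicit in the parameters.  The uniqueness
# condition checked here is the literal printed contraction test
#   1 - sigma^(1-alpha) L_i / Gamma(alpha) >= 0,
# which carries no horizon factor; the standard horizon-bearing variant
#   1 - sigma^(1-alpha) t^alpha L_i / Gamma(alpha+1) >= 0   (t = 1)
# is reported alongside as `flags_horizon` because the Picard demonstrator
# works on a unit horizon, where the two essentially coincide.

#' Default sup-norm bounds on the state box
#'
#' Generous envelopes of the trajectories seen in the therapy scenarios:
#' tumor is bounded by its carrying capacity, macrophage and dendritic
#' levels stay well below 2, CD4 below 10, and the probiotic below
#' `2 u1/vartheta + 1`.
#'
#' @param params A `"crc_params"` object.
#' @return Named numeric vector `(b1, b2, b3, b4, b5)`.
#' @export
default_state_bounds <- function(params) {
  c(b1 = params$s1, b2 = 2, b3 = 2, b4 = 10,
    b5 = 2 * params$u1 / params$vartheta + 1)
}

#' Sup-norm bounds realized by a trajectory
#'
#' @param traj A `"caputo_traj"` of the 5-state model.
#' @return Named numeric vector `(b1..b5)`: per-component max of `|x|`.
#' @export
bounds_from_trajectory <- function(traj) {
  stopifnot(inherits(traj, "caputo_traj"), ncol(traj$states) == 5L)
  setNames(apply(abs(traj$states), 2, max), paste0("b", 1:5))
}

#' Lipschitz constants and uniqueness flags
#'
#' On the box given by `bounds`, the kernels have Lipschitz constants
#' \deqn{L_1 = g_1 + u_3 + 2 b_1 g_1/s_1 + \beta_1 b_2/s_2 + \omega b_4/s_4,}
#' \eqn{L_2 = \beta_2 + d_1}, \eqn{L_3 = \beta_3 + d_2},
#' \eqn{L_4 = \beta_4 + d_3 + \delta + u_2}, \eqn{L_5 = \vartheta}.
#' The report carries the per-equation uniqueness flags
#' `1 - sigma^(1-alpha) L_i / Gamma(alpha) >= 0` (literal form, primary)
#' and the horizon-bearing variant at a unit horizon (`flags_horizon`),
#' plus `l_star = max(L_i)` and the comparison constant `bound_a`.
#'
#' @param params A `"crc_params"` object.
#' @param alpha Fractional order in (0, 1].
#' @param bounds Named vector `(b1..b5)` of nonnegative sup-norm bounds;
#'   default [default_state_bounds()].
#' @param sigma Time-rescaling constant, default 1.
#' @param bound_a Comparison constant dominating every `L_i`; default
#'   `1 + l_star`.
#' @return A `"lipschitz_report"`: list with `bounds`, `constants`
#'   (`L1..L5`), `l_star`, `bound_a`, `flags` (literal), `flags_horizon`,
#'   `alpha`, `sigma`.
#' @examples
#' p <- model_parameters(u1 = 0.2, u2 = 0.4, u3 = 0.5)
#' lipschitz_constants(p, alpha = 0.9)$constants
#' @export
lipschitz_constants <- function(params, alpha, bounds = default_state_bounds(params),
                                sigma = 1, bound_a = NULL) {
  check_alpha_sigma(alpha, sigma)
  p <- params
  bounds <- setNames(as.numeric(bounds), paste0("b", 1:5))
  stopifnot(all(bounds >= 0))
  L <- c(L1 = p$g1 + p$u3 + 2 * bounds[[1]] * p$g1 / p$s1 +
           p$beta1 * bounds[[2]] / p$s2 + p$omega * bounds[[4]] / p$s4,
         L2 = p$beta2 + p$d1,
         L3 = p$beta3 + p$d2,
         L4 = p$beta4 + p$d3 + p$delta + p$u2,
         L5 = p$vartheta)
  l_star <- max(L)
  if (is.null(bound_a)) bound_a <- 1 + l_star
  pref <- sigma^(1 - alpha)
  flags <- 1 - pref * L / gamma(alpha) >= 0
  flags_horizon <- 1 - pref * L / gamma(alpha + 1) >= 0
  structure(list(bounds = bounds, constants = L, l_star = l_star,
                 bound_a = bound_a,
                 flags = setNames(flags, names(L)),
                 flags_horizon = setNames(flags_horizon, names(L)),
                 alpha = alpha, sigma = sigma),
            class = "lipschitz_report")
}

#' @export
print.lipschitz_report <- function(x, ...) {
  cat(sprintf("<lipschitz_report> alpha = %g, sigma = %g, L* = %.4g (a = %.4g)\n",
              x$alpha, x$sigma, x$l_star, x$bound_a))
  print(x$constants)
  cat("uniqueness flags (literal):", paste(x$flags, collapse = " "), "\n")
  invisible(x)
}

#' Serialize a Lipschitz report to JSON
#'
#' @param x A `"lipschitz_report"`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
lipschitz_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "lipschitz_report"))
  js <- jsonlite::toJSON(list(bounds = as.list(x$bounds),
                              constants = as.list(x$constants),
                              l_star = x$l_star, bound_a = x$bound_a,
                              flags = as.list(x$flags),
                              flags_horizon = as.list(x$flags_horizon),
                              alpha = x$alpha, sigma = x$sigma),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Picard successive approximations of the Volterra integral form
#'
#' Demonstrates the fixed-point construction behind existence/uniqueness:
#' starting from the constant function \eqn{x_0(t) \equiv x_0}, each
#' iterate applies the fractional integral operator
#' \deqn{x_{n+1}(t_k) = x_0 + \frac{\sigma^{1-\alpha}}{\Gamma(\alpha)}
#'   \int_0^{t_k} K(x_n(\tau)) (t_k-\tau)^{\alpha-1} d\tau,}
#' discretized with the product-rectangle rule on the solver grid (exact
#' for a constant integrand).  The sup-norms of the successive differences
#' \eqn{\Psi_n = x_n - x_{n-1}} are recorded per component; under the
#' contraction conditions they shrink geometrically on a unit horizon.
#'
#' @param params A `"crc_params"` object.
#' @param y0 Initial state, see [state_vector()].
#' @param alpha Fractional order in (0, 1].
#' @param n_iter Number of Picard iterates (>= 2).
#' @param t_end Horizon, default 1 (the natural horizon for the literal
#'   contraction test).
#' @param n_steps Grid steps, default 200.
#' @param sigma Time-rescaling constant, default 1.
#' @param variant `"base"` or `"extended"`.
#' @return A `"picard_sequence"`: list with `times`, `iterates` (list of
#'   state matrices, `x_0` first), `psi_norms` (`n_iter` x 5 matrix of
#'   sup-norms of successive differences), `converged`, `blow_up`.
#' @examples
#' p <- model_parameters(u1 = 0.2)
#' ps <- picard_iterate(p, state_vector(), alpha = 0.9, n_iter = 6)
#' ps$psi_norms
#' @export
picard_iterate <- function(params, y0, alpha, n_iter, t_end = 1,
                           n_steps = 200L, sigma = 1,
                           variant = c("base", "extended")) {
  check_alpha_sigma(alpha, sigma)
  variant <- match.arg(variant)
  stopifnot(n_iter >= 2L, n_steps >= 1L, t_end > 0)
  field <- function(y) rhs_model(y, params, variant)
  n <- as.integer(n_steps)
  h <- t_end / n
  times <- seq(0, by = h, length.out = n + 1L)
  pref <- sigma^(1 - alpha) / gamma(alpha)
  x0row <- as_state(y0)
  cur <- matrix(rep(x0row, each = n + 1L), n + 1L, 5L,
                dimnames = list(NULL, .state_names))
  iterates <- list(cur)
  psi <- matrix(NA_real_, n_iter, 5L, dimnames = list(NULL, .state_names))
  blow_up <- FALSE
  for (it in seq_len(n_iter)) {
    K <- t(apply(cur, 1L, field))
    nxt <- matrix(0, n + 1L, 5L, dimnames = list(NULL, .state_names))
    nxt[1L, ] <- x0row
    for (k in seq_len(n)) {
      # product-rectangle rule: K held at the left node of each cell,
      # the power-law kernel integrated exactly over the cell
      j <- 0:(k - 1L)
      w <- ((k - j) * h)^alpha - ((k - 1L - j) * h)^alpha
      nxt[k + 1L, ] <- x0row + (pref / alpha) *
        colSums(w * K[1:k, , drop = FALSE])
    }
    psi[it, ] <- apply(abs(nxt - cur), 2L, max)
    iterates[[it + 1L]] <- nxt
    cur <- nxt
    if (any(!is.finite(cur)) || max(abs(cur)) > 1e12) {
      blow_up <- TRUE
      break
    }
  }
  ok <- stats::complete.cases(psi)
  converged <- !blow_up && sum(ok) >= 2L &&
    all(psi[max(which(ok)), ] <= psi[1L, ] + 1e-12)
  structure(list(times = times, iterates = iterates, psi_norms = psi,
                 converged = converged, blow_up = blow_up,
                 alpha = alpha, sigma = sigma),
            class = "picard_sequence")
}

#' @export
print.picard_sequence <- function(x, ...) {
  cat(sprintf("<picard_sequence> %d iterates, alpha = %g, converged: %s%s\n",
              length(x$iterates) - 1L, x$alpha, x$converged,
              if (x$blow_up) " (blow-up)" else ""))
  print(x$psi_norms)
  invisible(x)
}

#' Export Picard iterates as CSV files
#'
#' Writes one CSV per iterate (`<prefix>_iter<k>.csv`, header
#' `t,T,M,G,C,P`).
#'
#' @param x A `"picard_sequence"`.
#' @param prefix Path prefix for the output files.
#' @return Invisibly, the vector of file paths written.
#' @export
picard_to_csv <- function(x, prefix) {
  stopifnot(inherits(x, "picard_sequence"))
  paths <- character(0)
  for (k in seq_along(x$iterates)) {
    path <- sprintf("%s_iter%d.csv", prefix, k - 1L)
    write.csv(data.frame(t = x$times, x$iterates[[k]], check.names = FALSE),
              path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
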