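# Equilibria of the base model.
#
# The probiotic equation is linear and decoupled, so P* = u1/vartheta at any
# steady state.  The CD4 balance divides by
#   D_C = beta4 + d3 - u2 - delta*P*/(b + P*),
# which must be positive for an admissible (positive) CD4 level; D_C <= 0
# means immunotherapy plus probiotic recruitment outpace CD4 turnover and no
# finite equilibrium branch exists.

cd4_denominator <- function(params) {
  p <- params
  pstar <- p$u1 / p$vartheta
  p$beta4 + p$d3 - p$u2 - p$delta * pstar / (p$b + pstar)
}

#' Tumor-free equilibrium
#'
#' Closed-form steady state with `T = M = 0`:
#' \deqn{P^* = u_1/\vartheta,\quad G^* = r_1/(\beta_3+d_2),\quad
#'   C^* = (r_2 + g_4 G^*)/D_C,}
#' where \eqn{D_C = \beta_4 + d_3 - u_2 - \delta P^*/(b+P^*)}.  The
#' equilibrium exists (as a nonnegative state) iff \eqn{D_C > 0}; the
#' returned report always carries the max-norm residual of [rhs_base()] at
#' the state as an independent verification.
#'
#' @param params A `"crc_params"` object.
#' @return An `"equilibrium_report"`: list with `kind = "tumor_free"`,
#'   `state` (named 5-vector), `residual`, `exists`, `positive`, `notes`.
#' @seealso [find_coexistence()]
#' @examples
#' p <- model_parameters(g2 = 0.2, u1 = 0.2, u2 = 0.4, u3 = 0.5)
#' tumor_free_equilibrium(p)
#' @export
tumor_free_equilibrium <- function(params) {
  p <- params
  dc <- cd4_denominator(p)
  pstar <- p$u1 / p$vartheta
  gstar <- p$r1 / (p$beta3 + p$d2)
  if (dc <= 0) {
    return(new_equilibrium(
      kind = "tumor_free",
      state = c(T = 0, M = 0, G = gstar, C = NA_real_, P = pstar),
      residual = NA_real_, exists = FALSE, positive = FALSE,
      notes = "CD4 balance denominator nonpositive - no admissible tumor-free equilibrium"))
  }
  cstar <- (p$r2 + p$g4 * gstar) / dc
  state <- c(T = 0, M = 0, G = gstar, C = cstar, P = pstar)
  new_equilibrium(kind = "tumor_free", state = state,
                  residual = max(abs(rhs_base(state, p))),
                  exists = TRUE, positive = all(state >= 0), notes = "")
}

#' Scalar coexistence equation
#'
#' At a coexistence steady state (`T > 0`) the non-tumor components follow
#' from `T` by back-substitution:
#' `M*(T) = g2 T / ((beta2+d1)(s2+T))`,
#' `G*(T) = (r1 + g3 T/(s3+T)) / (beta3+d2)`,
#' `C*(T) = (r2 + g4 G*(T)) / D_C`, `P* = u1/vartheta`.
#' Dividing the tumor balance by `T` leaves one scalar equation whose
#' positive roots are the coexistence tumor levels:
#' \deqn{g_1(1 - T/s_1) - \beta_1 M^*(T)/(s_2+T) - \omega C^*(T)/(s_4+T) - u_3 = 0.}
#'
#' `mode = "corrected"` (default) evaluates that back-substituted reduction.
#' `mode = "paper_verbatim"` evaluates the printed variant of the scalar
#' equation, which substitutes the dendritic-cell branch `G*(T)` where the
#' CD4 branch belongs (an apparent label swap) and omits the `g4/D_C`
#' amplification; it is retained for documented comparison, and the
#' full-system residual arbitrates between the two (see
#' [find_coexistence()]).
#'
#' @param T Candidate tumor level(s), >= 0; vectorized.
#' @param params A `"crc_params"` object.
#' @param mode `"corrected"` or `"paper_verbatim"`.
#' @return Numeric vector of the scalar equation values.
#' @export
coexistence_scalar <- function(T, params, mode = c("corrected", "paper_verbatim")) {
  mode <- match.arg(mode)
  p <- params
  stopifnot(all(T >= 0))
  if (mode == "corrected") {
    dc <- cd4_denominator(p)
    if (dc <= 0) stop("no admissible C branch: CD4 balance denominator nonpositive")
    mstar <- p$g2 * T / ((p$beta2 + p$d1) * (p$s2 + T))
    gstar <- (p$r1 + p$g3 * T / (p$s3 + T)) / (p$beta3 + p$d2)
    cstar <- (p$r2 + p$g4 * gstar) / dc
    p$g1 * (1 - T / p$s1) - p$beta1 * mstar / (p$s2 + T) -
      p$omega * cstar / (p$s4 + T) - p$u3
  } else {
    p$g1 * (1 - T / p$s1) -
      p$beta1 * p$g2 * T / ((p$beta2 + p$d1) * (p$s2 + T)^2) -
      (p$omega * p$r1 * (p$s3 + T) + p$omega * p$g3 * T) /
        ((p$beta3 + p$d2) * (p$s3 + T) * (p$s4 + T)) -
      p$u3
  }
}

#' Find coexistence equilibria by scalar root-finding
#'
#' Scans [coexistence_scalar()] on a uniform grid over (0, `s1`], brackets
#' every sign change, polishes each bracket with [stats::uniroot()] to
#' `|f| < 1e-12`, back-substitutes the remaining components and verifies
#' the full-system residual with [rhs_base()].  Roots closer than
#' `1e-6 * s1` are merged; non-finite or negative back-substituted states
#' are discarded with a note.
#'
#' @inheritParams coexistence_scalar
#' @param scan_points Number of scan-grid points (>= 100, default 10000).
#' @return A list of `"equilibrium_report"` objects (possibly empty), one
#'   per admissible coexistence equilibrium.
#' @examples
#' p <- model_parameters(g2 = 0.6, u1 = 0.3, u2 = 0.2, u3 = 0.01)
#' eqs <- find_coexistence(p)
#' if (length(eqs)) eqs[[1]]$state
#' @export
find_coexistence <- function(params, mode = c("corrected", "paper_verbatim"),
                             scan_points = 10000L) {
  mode <- match.arg(mode)
  p <- params
  stopifnot(scan_points >= 100L)
  grid <- seq(p$s1 / scan_points, p$s1, length.out = scan_points)
  fx <- coexistence_scalar(grid, p, mode)
  roots <- numeric(0)
  exact <- grid[fx == 0]
  roots <- c(roots, exact)
  sgn <- sign(fx)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flips) {
    r <- uniroot(function(x) coexistence_scalar(x, p, mode),
                 lower = grid[i], upper = grid[i + 1],
                 tol = .Machine$double.eps^0.9)$root
    roots <- c(roots, r)
  }
  roots <- sort(roots)
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-6 * p$s1)]
  lapply(roots, function(tstar) coexistence_report(tstar, p))
}

coexistence_report <- function(tstar, p) {
  dc <- cd4_denominator(p)
  pstar <- p$u1 / p$vartheta
  mstar <- p$g2 * tstar / ((p$beta2 + p$d1) * (p$s2 + tstar))
  gstar <- (p$r1 + p$g3 * tstar / (p$s3 + tstar)) / (p$beta3 + p$d2)
  cstar <- (p$r2 + p$g4 * gstar) / dc
  state <- c(T = tstar, M = mstar, G = gstar, C = cstar, P = pstar)
  if (!all(is.finite(state)) || any(state < 0)) {
    return(new_equilibrium(kind = "coexistence", state = state,
                           residual = NA_real_, exists = FALSE,
                           positive = FALSE,
                           notes = "back-substituted component negative or non-finite"))
  }
  res <- max(abs(rhs_base(state, p)))
  new_equilibrium(kind = "coexistence", state = state, residual = res,
                  exists = res < 1e-9, positive = all(state > 0),
                  notes = if (res < 1e-9) "" else
                    sprintf("residual %.3g exceeds tolerance", res))
}

new_equilibrium <- function(kind, state, residual, exists, positive, notes) {
  structure(list(kind = kind, state = state, residual = residual,
                 exists = exists, positive = positive, notes = notes),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("<equilibrium_report> %s (exists: %s, residual: %s)\n",
              x$kind, x$exists,
              if (is.na(x$residual)) "NA" else format(x$residual, digits = 3)))
  print(x$state)
  if (nzchar(x$notes)) cat("note:", x$notes, "\n")
  invisible(x)
}

#' Serialize an equilibrium report to JSON
#'
#' @param x An `"equilibrium_report"`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
equilibrium_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "equilibrium_report"))
  js <- jsonlite::toJSON(list(kind = x$kind, state = as.list(x$state),
                              residual = x$residual, exists = x$exists,
                              positive = x$positive, notes = x$notes),
                         auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
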