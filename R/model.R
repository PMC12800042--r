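#' Right-hand side of the base tumor--immune--probiotic model
#'
#' Evaluates the five rate kernels of the base model at one state.  With
#' constant dose rates the system is autonomous, so no time argument is
#' needed.  The equations are
#' \deqn{K_1 = g_1 T (1 - T/s_1) - \beta_1 T M/(s_2+T) - \omega T C/(s_4+T) - u_3 T}
#' \deqn{K_2 = g_2 T/(s_2+T) - (\beta_2+d_1) M}
#' \deqn{K_3 = r_1 + g_3 T/(s_3+T) - (\beta_3+d_2) G}
#' \deqn{K_4 = r_2 + g_4 G - (\beta_4+d_3) C + \delta P C/(b+P) + u_2 C}
#' \deqn{K_5 = u_1 - \vartheta P}
#'
#' @param state Named 5-vector `(T, M, G, C, P)`; see [state_vector()].
#' @param params A `"crc_params"` object.
#' @return Numeric 5-vector of rates, named `(T, M, G, C, P)`.
#' @seealso [rhs_extended()], [scaled_rhs()], [simulate_model()]
#' @examples
#' p <- model_parameters(u1 = 0.2, u2 = 0.4, u3 = 0.5)
#' rhs_base(state_vector(), p)    # (0, 0, r1, r2, u1) at the origin
#' @export
rhs_base <- function(state, params) {
  s <- as_state(state)
  T <- s[[1]]; M <- s[[2]]; G <- s[[3]]; C <- s[[4]]; P <- s[[5]]
  p <- params
  if (p$s2 + T <= 0 || p$s3 + T <= 0 || p$s4 + T <= 0 || p$b + P <= 0)
    stop("saturation denominator is nonpositive")
  c(T = p$g1 * T * (1 - T / p$s1) - p$beta1 * T * M / (p$s2 + T) -
        p$omega * T * C / (p$s4 + T) - p$u3 * T,
    M = p$g2 * T / (p$s2 + T) - (p$beta2 + p$d1) * M,
    G = p$r1 + p$g3 * T / (p$s3 + T) - (p$beta3 + p$d2) * G,
    C = p$r2 + p$g4 * G - (p$beta4 + p$d3) * C +
        p$delta * P * C / (p$b + P) + p$u2 * C,
    P = p$u1 - p$vartheta * P)
}

#' Right-hand side of the extended model
#'
#' Adds three cross-recruitment terms to the base model: macrophage
#' recruitment by CD4+ T cells (`g5 C/(s2+C)` in the M-equation) and
#' dendritic-cell recruitment by macrophages and CD4+ T cells
#' (`g6 M/(s3+M) + g7 C/(s3+C)` in the G-equation).  With
#' `g5 = g6 = g7 = 0` the output equals [rhs_base()] exactly.
#'
#' @inheritParams rhs_base
#' @return Numeric 5-vector of rates.
#' @export
rhs_extended <- function(state, params) {
  s <- as_state(state)
  out <- rhs_base(s, params)
  p <- params
  M <- s[[2]]; C <- s[[4]]
  out[["M"]] <- out[["M"]] + p$g5 * C / (p$s2 + C)
  out[["G"]] <- out[["G"]] + p$g6 * M / (p$s3 + M) + p$g7 * C / (p$s3 + C)
  out
}

#' @rdname rhs_base
#' @param variant `"base"` or `"extended"`.
#' @export
rhs_model <- function(state, params, variant = c("base", "extended")) {
  variant <- match.arg(variant)
  if (variant == "base") rhs_base(state, params) else rhs_extended(state, params)
}

#' Sigma-scaled right-hand side
#'
#' The dimensional-consistency form of the model divides the Caputo
#' derivative by \eqn{\sigma^{1-\alpha}}; moving the prefactor to the other
#' side gives \eqn{D^\alpha x = \sigma^{1-\alpha} f(x)}.  This helper
#' evaluates that scaled field.  At `alpha = 1` (or `sigma = 1`) it equals
#' the unscaled right-hand side.
#'
#' @inheritParams rhs_model
#' @param alpha Fractional order in (0, 1].
#' @param sigma Time-rescaling constant (> 0), default 1.
#' @return Numeric 5-vector: `sigma^(1 - alpha) * rhs`.
#' @export
scaled_rhs <- function(state, params, alpha, sigma = 1,
                       variant = c("base", "extended")) {
  check_alpha_sigma(alpha, sigma)
  sigma^(1 - alpha) * rhs_model(state, params, match.arg(variant))
}

check_alpha_sigma <- function(alpha, sigma) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("alpha must be a single number in (0, 1]")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a single positive number")
  invisible(TRUE)
}
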