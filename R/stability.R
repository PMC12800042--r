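# Linearized stability analysis.
#
# Two Jacobian modes are kept side by side.  "correct" is the exact partial
# derivative matrix of the right-hand side and is the default; tests verify
# it against central finite differences.  "paper_verbatim" reproduces the
# literature's printed linearization, whose entries differ from direct
# differentiation in four places (stray (1 - T*) and (1 - P*) factors and a
# squared saturation constant in the tumor-kill column); it is retained so
# the discrepancy is reproducible, never used for classification.

#' Jacobian of the model
#'
#' Returns the 5x5 linearization of the base or extended right-hand side at
#' a state.  `mode = "correct"` differentiates the rates exactly (a
#' saturating term `a x/(s+x)` has derivative `a s/(s+x)^2`; the probiotic
#' recruitment `delta P C/(b+P)` has P-derivative `delta b C/(b+P)^2`).
#' `mode = "paper_verbatim"` evaluates the printed entries literally and is
#' only available for the base variant.
#'
#' @param params A `"crc_params"` object.
#' @param state Named 5-vector, see [state_vector()].
#' @param mode `"correct"` (default) or `"paper_verbatim"`.
#' @param variant `"base"` or `"extended"`.
#' @return 5x5 numeric matrix with rows/columns named `T, M, G, C, P`.
#' @export
jacobian_matrix <- function(params, state, mode = c("correct", "paper_verbatim"),
                            variant = c("base", "extended")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  s <- as_state(state)
  if (!all(is.finite(s))) stop("state must be finite")
  p <- params
  T <- s[[1]]; M <- s[[2]]; G <- s[[3]]; C <- s[[4]]; P <- s[[5]]
  J <- matrix(0, 5, 5, dimnames = list(.state_names, .state_names))
  if (mode == "correct") {
    J[1, 1] <- p$g1 * (1 - 2 * T / p$s1) -
      p$beta1 * M * p$s2 / (p$s2 + T)^2 -
      p$omega * C * p$s4 / (p$s4 + T)^2 - p$u3
    J[1, 2] <- -p$beta1 * T / (p$s2 + T)
    J[1, 4] <- -p$omega * T / (p$s4 + T)
    J[2, 1] <- p$g2 * p$s2 / (p$s2 + T)^2
    J[2, 2] <- -(p$beta2 + p$d1)
    J[3, 1] <- p$g3 * p$s3 / (p$s3 + T)^2
    J[3, 3] <- -(p$beta3 + p$d2)
    J[4, 3] <- p$g4
    J[4, 4] <- -(p$beta4 + p$d3) + p$u2 + p$delta * P / (p$b + P)
    J[4, 5] <- p$delta * p$b * C / (p$b + P)^2
    J[5, 5] <- -p$vartheta
    if (variant == "extended") {
      J[2, 4] <- J[2, 4] + p$g5 * p$s2 / (p$s2 + C)^2
      J[3, 2] <- J[3, 2] + p$g6 * p$s3 / (p$s3 + M)^2
      J[3, 4] <- J[3, 4] + p$g7 * p$s3 / (p$s3 + C)^2
    }
  } else {
    if (variant == "extended")
      stop("paper_verbatim mode is only defined for the base variant")
    J[1, 1] <- p$g1 - p$u3 - 2 * p$g1 * T / p$s1 -
      p$beta1 * M * (1 - T) / (p$s2 + T)^2 -
      p$omega * C * (1 - T) / (p$s4 + T)^2
    J[1, 2] <- -p$beta1 * T / (p$s2 + T)
    J[1, 4] <- -p$omega * T / (p$s4 + T)
    J[2, 1] <- p$g2 * (1 - T) / (p$s2 + T)^2
    J[2, 2] <- -(p$beta2 + p$d1)
    J[3, 1] <- p$g3 * (1 - T) / (p$s3 + T)^2
    J[3, 3] <- -(p$beta3 + p$d2)
    J[4, 3] <- p$g4
    J[4, 4] <- -(p$beta4 + p$d3) + p$u2 + p$delta * P / (p$b + P)
    J[4, 5] <- p$delta * C * (1 - P) / (p$b + P)^2
    J[5, 5] <- -p$vartheta
  }
  J
}

#' Eigenvalues of a Jacobian
#'
#' @param jac Square numeric matrix.
#' @return Complex vector of eigenvalues.
#' @export
jacobian_eigenvalues <- function(jac) {
  stopifnot(is.matrix(jac), all(is.finite(jac)))
  eigen(jac, only.values = TRUE)$values
}

#' Characteristic coefficients of the coupled 4x4 block
#'
#' The probiotic row of the Jacobian decouples (its only nonzero entry is
#' the diagonal `-vartheta`), so four eigenvalues come from the block over
#' `(T, M, G, C)`.  Writing that block's entries as `A1..A9` (the sparsity
#' the model always produces: zeros at the `(T,G)`, `(M,G)`, `(M,C)`,
#' `(G,M)`, `(G,C)`, `(C,T)` and `(C,M)` positions), the characteristic
#' polynomial is
#' \deqn{\lambda^4 - R_1\lambda^3 + R_2\lambda^2 + R_3\lambda + R_4}
#' with
#' `R1 = A1+A5+A7+A9`,
#' `R2 = A1A5 + A1A7 + A1A9 + A5A7 + A5A9 + A7A9 - A2A4`,
#' `R3 = -(A1A5A7 + A1A5A9 + A1A7A9 + A5A7A9) + A2A4(A7+A9) - A3A6A8`,
#' `R4 = A1A5A7A9 - A2A4A7A9 + A3A5A6A8`.
#'
#' @param jac 5x5 model Jacobian (the `(T,M,G,C)` block is extracted) or a
#'   4x4 block directly.
#' @return Named numeric vector `(R1, R2, R3, R4)`.  The monic polynomial
#'   coefficients are `c(1, -R1, R2, R3, R4)`.
#' @export
block_characteristic_coeffs <- function(jac) {
  stopifnot(is.matrix(jac), all(is.finite(jac)))
  B <- if (all(dim(jac) == c(5L, 5L))) jac[1:4, 1:4] else jac
  stopifnot(all(dim(B) == c(4L, 4L)))
  A1 <- B[1, 1]; A2 <- B[1, 2]; A3 <- B[1, 4]
  A4 <- B[2, 1]; A5 <- B[2, 2]
  A6 <- B[3, 1]; A7 <- B[3, 3]
  A8 <- B[4, 3]; A9 <- B[4, 4]
  c(R1 = A1 + A5 + A7 + A9,
    R2 = A1 * A5 + A7 * A1 + A7 * A5 + A9 * A1 + A9 * A5 + A7 * A9 - A2 * A4,
    R3 = -A7 * A1 * A5 - A9 * A1 * A5 - A7 * A9 * A1 - A7 * A9 * A5 +
      A2 * A4 * (A7 + A9) - A3 * A6 * A8,
    R4 = A7 * A9 * A1 * A5 - A2 * A4 * A7 * A9 + A3 * A6 * A8 * A5)
}

#' Hurwitz determinants of the block characteristic polynomial
#'
#' For the quartic \eqn{\lambda^4 - R_1\lambda^3 + R_2\lambda^2 + R_3\lambda
#' + R_4} the leading principal minors of the Hurwitz matrix are
#' `H1 = -R1`, `H2 = -R1 R2 - R3`, `H3 = -R1 R2 R3 - R1^2 R4 - R3^2` and
#' `H4 = R4 H3`.  All four positive is the Routh--Hurwitz condition for
#' every block eigenvalue to have negative real part.
#'
#' @param R Numeric vector `(R1, R2, R3, R4)`, e.g. from
#'   [block_characteristic_coeffs()].
#' @return Named numeric vector `(H1, H2, H3, H4)`.
#' @export
hurwitz_determinants <- function(R) {
  stopifnot(length(R) == 4L, all(is.finite(R)))
  R1 <- R[[1]]; R2 <- R[[2]]; R3 <- R[[3]]; R4 <- R[[4]]
  H1 <- -R1
  H2 <- -R1 * R2 - R3
  H3 <- -R1 * R2 * R3 - R1^2 * R4 - R3^2
  c(H1 = H1, H2 = H2, H3 = H3, H4 = R4 * H3)
}

#' Matignon stability classification for fractional linear systems
#'
#' A Caputo system of order `alpha` is locally asymptotically stable at an
#' equilibrium iff every Jacobian eigenvalue satisfies
#' \eqn{|\arg \lambda| > \alpha \pi/2}.  At `alpha = 1` this reduces to the
#' classical negative-real-part condition.  Eigenvalues whose argument lies
#' within `tol` of the critical cone (including zero eigenvalues) classify
#' as `"marginal"`, never `"stable"`.
#'
#' @param eigenvalues Complex (or real) vector of eigenvalues.
#' @param alpha Fractional order in (0, 1].
#' @param tol Marginality band on the argument (radians), default 1e-8.
#' @return List with `classification` (`"stable"`, `"unstable"` or
#'   `"marginal"`) and `margin` = min over eigenvalues of
#'   `|arg(lambda)| - alpha*pi/2`.
#' @export
matignon_classify <- function(eigenvalues, alpha, tol = 1e-8) {
  check_alpha_sigma(alpha, 1)
  lam <- as.complex(eigenvalues)
  args <- abs(Arg(lam))
  args[Mod(lam) == 0] <- 0   # a zero eigenvalue sits on the cone apex
  per <- args - alpha * pi / 2
  # eigenvalues within tol of the origin are within tol of the critical
  # cone's apex whatever their argument: boundary cases, never decisive
  per[Mod(lam) <= tol] <- 0
  margin <- min(per)
  cls <- if (margin > tol) "stable" else if (margin < -tol) "unstable" else "marginal"
  list(classification = cls, margin = margin)
}

#' Full stability assessment of an equilibrium
#'
#' Linearizes the base model at an equilibrium, computes eigenvalues, the
#' block characteristic coefficients `R1..R4` and Hurwitz determinants
#' `H1..H4`, evaluates the named theorem conditions (for the tumor-free
#' equilibrium: the tumor and CD4 eigenvalues negative; for coexistence:
#' the four Hurwitz sign conditions), classifies stability by the Matignon
#' criterion at the requested `alpha`, and records the
#' Hurwitz-vs-eigenvalue cross-check.
#'
#' @param params A `"crc_params"` object.
#' @param equilibrium An `"equilibrium_report"` with `exists = TRUE`.
#' @param alpha Fractional order in (0, 1].
#' @param mode Jacobian mode, `"correct"` (default) or `"paper_verbatim"`.
#' @return A `"stability_report"`: list with `jacobian`, `eigenvalues`,
#'   `block_coeffs`, `hurwitz`, `theorem_conditions` (named logicals),
#'   `matignon_margin`, `classification`, `hurwitz_eigen_agree`,
#'   `jacobian_mode`, `alpha`.
#' @examples
#' p <- model_parameters(g2 = 0.2, u1 = 0.2, u2 = 0.4, u3 = 0.5)
#' rep <- assess_equilibrium(p, tumor_free_equilibrium(p), alpha = 0.9)
#' rep$classification
#' @export
assess_equilibrium <- function(params, equilibrium, alpha,
                               mode = c("correct", "paper_verbatim")) {
  mode <- match.arg(mode)
  stopifnot(inherits(equilibrium, "equilibrium_report"))
  if (!isTRUE(equilibrium$exists))
    stop("equilibrium does not exist; nothing to assess")
  J <- jacobian_matrix(params, equilibrium$state, mode = mode)
  lam <- jacobian_eigenvalues(J)
  R <- block_characteristic_coeffs(J)
  H <- hurwitz_determinants(R)
  if (equilibrium$kind == "tumor_free") {
    # closed-form tumor and CD4 eigenvalues at E1* (correct-mode entries)
    lam_tumor <- J[1, 1]
    lam_cd4 <- J[4, 4]
    conds <- c(tumor_eigen_negative = lam_tumor < 0,
               cd4_eigen_negative = lam_cd4 < 0)
  } else {
    conds <- c(H1_positive = H[["H1"]] > 0, H2_positive = H[["H2"]] > 0,
               H3_positive = H[["H3"]] > 0, H4_positive = H[["H4"]] > 0)
  }
  mat <- matignon_classify(lam, alpha)
  block_lam <- jacobian_eigenvalues(J[1:4, 1:4])
  agree <- all(H > 0) == all(Re(block_lam) < 0)
  structure(list(jacobian = J, eigenvalues = lam, block_coeffs = R,
                 hurwitz = H, theorem_conditions = conds,
                 matignon_margin = mat$margin,
                 classification = mat$classification,
                 hurwitz_eigen_agree = agree,
                 jacobian_mode = mode, alpha = alpha,
                 equilibrium = equilibrium),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s equilibrium, alpha = %g: %s (margin %.4g)\n",
              x$equilibrium$kind, x$alpha, x$classification, x$matignon_margin))
  cat("eigenvalues:\n"); print(x$eigenvalues)
  cat("theorem conditions:\n"); print(x$theorem_conditions)
  invisible(x)
}

#' Serialize a stability report to JSON
#'
#' Matrices are written row-major.
#'
#' @param x A `"stability_report"`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
stability_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "stability_report"))
  js <- jsonlite::toJSON(list(
    jacobian = as.vector(t(x$jacobian)),
    eigenvalues_re = Re(x$eigenvalues), eigenvalues_im = Im(x$eigenvalues),
    block_coeffs = as.list(x$block_coeffs), hurwitz = as.list(x$hurwitz),
    theorem_conditions = as.list(x$theorem_conditions),
    matignon_margin = x$matignon_margin,
    classification = x$classification,
    jacobian_mode = x$jacobian_mode, alpha = x$alpha),
    auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
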