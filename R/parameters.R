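#' Model parameters for the tumor--immune--probiotic system
#'
#' Constructs the full parameter set of the five-compartment colon-cancer
#' model: tumor cells `T`, macrophages `M`, dendritic cells `G`, CD4+ T helper
#' cells `C` and probiotic drug concentration `P`.  Fixed parameters default
#' to their tabulated literature values; the five ranged parameters
#' (`g1`, `g2`, `g3`, `g4`, `delta`) default to the baseline therapy scenario
#' and are the ones a user typically varies.  The extended-model recruitment
#' rates `g5`, `g6`, `g7` default to 0, which reduces the system to the base
#' model exactly.
#'
#' Tabulated ranges for the varied parameters are `g1` in \[0.1, 0.9\],
#' `g2` in \[0.2, 0.9\], `g3` in \[0.2, 0.9\], `g4` in \[0.1, 0.9\] and
#' `delta` in \[0.15, 0.60\].  Values outside these ranges trigger a warning,
#' not an error, because sweep studies deliberately step across them.
#'
#' @param g1 Intrinsic tumor growth rate (1/time).
#' @param g2 Recruitment rate of macrophages by tumor cells.
#' @param g3 Recruitment rate of dendritic cells by tumor cells.
#' @param g4 Activation rate of CD4+ T cells by dendritic cells.
#' @param delta Recruitment rate of CD4+ T cells by the probiotic.
#' @param u1,u2,u3 Constant dose rates of the probiotic, immunotherapeutic
#'   and chemotherapy drugs.
#' @param s1 Tumor carrying capacity (cells).
#' @param s2,s3,s4 Half-saturation constants (cells) for the macrophage,
#'   dendritic and CD4+ interaction terms.
#' @param r1 Baseline dendritic cell production rate (cells/time).
#' @param r2 Baseline CD4+ T cell production rate (cells/time).
#' @param beta1 Tumor kill rate by macrophages (1/time).
#' @param omega Tumor kill rate by CD4+ T cells (1/time).
#' @param beta2,beta3,beta4 Natural death rates of M, G, C (1/time).
#' @param d1,d2,d3 Chemotherapy-induced death rates of M, G, C (1/time).
#' @param vartheta Probiotic decay rate (1/time), strictly positive.
#' @param b Probiotic half-saturation constant (concentration).
#' @param g5,g6,g7 Extended-model recruitment rates (macrophages by CD4+
#'   cells, dendritic cells by macrophages, dendritic cells by CD4+ cells);
#'   all 0 in the base model.
#'
#' @return An object of class `"crc_params"`: a named list of numeric
#'   scalars, validated for nonnegativity and positivity of the saturation
#'   and decay constants.
#' @seealso [rhs_base()], [read_params_config()], [draw_parameters()]
#' @examples
#' p <- model_parameters()
#' p$s1
#' p2 <- model_parameters(g2 = 0.6, u1 = 0.3, u2 = 0.2, u3 = 0.01)
#' @export
model_parameters <- function(g1 = 0.1, g2 = 0.2, g3 = 0.3, g4 = 0.1,
                             delta = 0.15,
                             u1 = 0, u2 = 0, u3 = 0,
                             s1 = 1000, s2 = 50, s3 = 50, s4 = 50,
                             r1 = 0.3, r2 = 0.7,
                             beta1 = 0.1, omega = 0.3,
                             beta2 = 0.5, beta3 = 0.4, beta4 = 0.7,
                             d1 = 0.008, d2 = 0.0008, d3 = 0.0001,
                             vartheta = 1, b = 0.25,
                             g5 = 0, g6 = 0, g7 = 0) {
  p <- list(g1 = g1, g2 = g2, g3 = g3, g4 = g4, delta = delta,
            u1 = u1, u2 = u2, u3 = u3,
            s1 = s1, s2 = s2, s3 = s3, s4 = s4,
            r1 = r1, r2 = r2,
            beta1 = beta1, omega = omega,
            beta2 = beta2, beta3 = beta3, beta4 = beta4,
            d1 = d1, d2 = d2, d3 = d3,
            vartheta = vartheta, b = b,
            g5 = g5, g6 = g6, g7 = g7)
  validate_params(p)
}

#' Default (baseline-scenario) parameter set
#'
#' Convenience wrapper around [model_parameters()]; arguments override any
#' field.  Returns the tabulated fixed values with the ranged parameters at
#' their baseline settings and the extended-model terms switched off.
#'
#' @param ... Named overrides passed to [model_parameters()].
#' @return A `"crc_params"` object.
#' @examples
#' default_parameters()$d3
#' @export
default_parameters <- function(...) {
  model_parameters(...)
}

.param_names <- c("g1", "g2", "g3", "g4", "delta", "u1", "u2", "u3",
                  "s1", "s2", "s3", "s4", "r1", "r2",
                  "beta1", "omega", "beta2", "beta3", "beta4",
                  "d1", "d2", "d3", "vartheta", "b", "g5", "g6", "g7")

.param_ranges <- list(g1 = c(0.1, 0.9), g2 = c(0.2, 0.9), g3 = c(0.2, 0.9),
                      g4 = c(0.1, 0.9), delta = c(0.15, 0.60))

validate_params <- function(p) {
  miss <- setdiff(.param_names, names(p))
  if (length(miss))
    stop("missing parameters: ", paste(miss, collapse = ", "))
  p <- p[.param_names]
  vals <- unlist(p)
  if (!all(is.finite(vals)))
    stop("all parameters must be finite numbers")
  if (any(vals < 0))
    stop("all parameters must be nonnegative; negative: ",
         paste(names(vals)[vals < 0], collapse = ", "))
  strict <- c("s1", "s2", "s3", "s4", "b", "vartheta")
  if (any(vals[strict] <= 0))
    stop("parameters ", paste(strict[vals[strict] <= 0], collapse = ", "),
         " must be strictly positive")
  for (nm in names(.param_ranges)) {
    rg <- .param_ranges[[nm]]
    if (p[[nm]] < rg[1] || p[[nm]] > rg[2])
      warning(sprintf("%s = %g lies outside the tabulated range [%g, %g]",
                      nm, p[[nm]], rg[1], rg[2]), call. = FALSE)
  }
  structure(p, class = "crc_params")
}

#' @export
print.crc_params <- function(x, ...) {
  cat("Tumor-immune-probiotic model parameters\n")
  v <- unlist(x)
  ext <- v[c("g5", "g6", "g7")]
  cat(sprintf("  variant: %s\n",
              if (any(ext > 0)) "extended (g5/g6/g7 active)" else "base"))
  print(v)
  invisible(x)
}

#' State vector of the model
#'
#' Bundles one time point of the five compartments into a validated named
#' numeric vector.  Components must be finite and nonnegative at
#' construction; the integrator itself never clamps.
#'
#' @param T Tumor cells.
#' @param M Macrophages.
#' @param G Dendritic cells.
#' @param C CD4+ T helper cells.
#' @param P Probiotic drug concentration.
#' @return Named numeric vector `c(T, M, G, C, P)`.
#' @examples
#' state_vector(10, 0, 0, 0, 0)
#' @export
state_vector <- function(T = 0, M = 0, G = 0, C = 0, P = 0) {
  x <- c(T = T, M = M, G = G, C = C, P = P)
  if (!all(is.finite(x))) stop("state components must be finite")
  if (any(x < 0)) stop("state components must be nonnegative")
  x
}

.state_names <- c("T", "M", "G", "C", "P")

as_state <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 5L) stop("a model state has exactly 5 components")
  names(x) <- .state_names
  x
}

#' Read or write a flat key-value parameter configuration
#'
#' Configuration files hold one `key = value` pair per line (alternatively
#' `key: value`; blank lines and `#` comments are ignored).  Keys are the
#' parameter names of [model_parameters()] plus, optionally, `alpha` and
#' `sigma`.  `read_params_config()` returns the parameter object together
#' with any `alpha`/`sigma` found; `write_params_config()` writes all
#' parameter fields and, if supplied, `alpha` and `sigma`.
#'
#' @param path File path.
#' @param params A `"crc_params"` object.
#' @param alpha,sigma Optional fractional order and time-rescaling constant
#'   to store alongside the parameters.
#' @return For `read_params_config()`, a list with elements `params`
#'   (`"crc_params"`), `alpha` (or `NULL`) and `sigma` (or `NULL`).
#'   `write_params_config()` invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".cfg")
#' write_params_config(model_parameters(), f, alpha = 0.9)
#' cfg <- read_params_config(f)
#' cfg$alpha
#' @export
read_params_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- lapply(lines, function(l) {
    parts <- strsplit(l, "[=:]", fixed = FALSE)[[1]]
    if (length(parts) != 2L)
      stop("malformed config line: '", l, "'")
    c(trimws(parts[1]), trimws(parts[2]))
  })
  keys <- vapply(kv, `[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
  if (anyNA(vals))
    stop("non-numeric config values for: ",
         paste(keys[is.na(vals)], collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicate config keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  known <- c(.param_names, "alpha", "sigma")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  named <- as.list(setNames(vals, keys))
  pl <- named[intersect(keys, .param_names)]
  params <- do.call(model_parameters, pl)
  list(params = params,
       alpha = named[["alpha"]],
       sigma = named[["sigma"]])
}

#' @rdname read_params_config
#' @export
write_params_config <- function(params, path, alpha = NULL, sigma = NULL) {
  stopifnot(inherits(params, "crc_params"))
  out <- sprintf("%s = %.17g", names(params), unlist(params))
  if (!is.null(alpha)) out <- c(out, sprintf("alpha = %.17g", alpha))
  if (!is.null(sigma)) out <- c(out, sprintf("sigma = %.17g", sigma))
  writeLines(out, path)
  invisible(path)
}
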