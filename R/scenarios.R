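# Scenario registry.
#
# Each entry reproduces one published numerical experiment verbatim: the
# parameter set, initial state(s), fractional orders, dose triples or sweep
# values are stored exactly as printed.  Horizons and step counts are not
# stated in the source experiments; the defaults below are chosen so that
# every component settles on the horizon (from the linearized relaxation
# rates, including the algebraic t^(-alpha) fractional tails) with
# h <= 0.05 for the short transient runs and h in [0.1, 0.2] for the two
# long-horizon runs dominated by slow modes (all local rates there are
# well below 1/h, so the coarser step costs no visible accuracy).

scenario_table <- function() {
  base1 <- list(g1 = 0.1, g3 = 0.3, g4 = 0.1, delta = 0.15)
  list(
    app1_i = list(
      name = "app1_i", variant = "base",
      params = do.call(model_parameters,
                       c(base1, list(g2 = 0.2, u1 = 0.2, u2 = 0.4, u3 = 0.5))),
      initial = list(c(10, 0, 0, 0, 0)),
      alphas = c(0.75, 0.80, 0.85, 0.90, 1),
      doses = NULL, sweep = NULL,
      t_end = 800, n_steps = 16000L),
    app1_ii = list(
      name = "app1_ii", variant = "base",
      params = do.call(model_parameters,
                       c(base1, list(g2 = 0.6, u1 = 0.3, u2 = 0.2, u3 = 0.01))),
      initial = list(c(10, 0, 0, 0, 0)),
      alphas = c(0.60, 0.70, 0.80, 0.90, 1),
      doses = NULL, sweep = NULL,
      t_end = 500, n_steps = 10000L),
    app2_i = list(
      name = "app2_i", variant = "base",
      params = do.call(model_parameters,
                       c(base1, list(g2 = 0.2, u1 = 0.1, u2 = 0.6, u3 = 0.5))),
      initial = list(c(10, 0, 0, 0, 0), c(6, 2, 4, 6, 1), c(13, 4, 8, 12, 2),
                     c(15, 6, 12, 0, 3), c(17, 8, 16, 20, 4)),
      alphas = 0.96,
      doses = NULL, sweep = NULL,
      t_end = 8000, n_steps = 80000L),
    app2_ii = list(
      name = "app2_ii", variant = "base",
      params = do.call(model_parameters, c(base1, list(g2 = 0.2))),
      initial = list(c(10, 0, 0, 0, 0)),
      alphas = 0.90,
      doses = list(c(0.5, 0.5, 0.5), c(0.4, 0.5, 0.3), c(0.6, 0.3, 0.4),
                   c(0.2, 0.4, 0.2), c(0.1, 0.2, 0.1)),
      sweep = NULL,
      t_end = 3000, n_steps = 15000L),
    app3 = list(
      name = "app3", variant = "extended",
      params = do.call(model_parameters,
                       c(base1, list(g2 = 0.2, u1 = 0.2, u2 = 0.4, u3 = 0.5,
                                     g5 = 0.1, g6 = 0.15, g7 = 0.2))),
      initial = list(c(10, 0, 0, 0, 0)),
      alphas = 0.90,
      doses = NULL,
      sweep = list(g1 = c(0.1, 0.3, 0.5, 0.7, 0.9),
                   g2 = c(0.2, 0.3, 0.5, 0.7, 0.9),
                   g3 = c(0.2, 0.3, 0.5, 0.7, 0.9),
                   g4 = c(0.1, 0.3, 0.5, 0.7, 0.9),
                   delta = c(0.15, 0.25, 0.40, 0.50, 0.60)),
      sweep_initial = list(delta = c(10, 0, 10, 40, 40)),
      t_end = 200, n_steps = 4000L)
  )
}

#' List or fetch registered therapy scenarios
#'
#' Five scenarios are registered: `app1_i` (tumor clearance under full
#' triple dosing, varying fractional order), `app1_ii` (tumor--immune
#' coexistence under low chemotherapy, varying order), `app2_i` (five
#' initial states, common attractor), `app2_ii` (five dose triples),
#' `app3` (extended model, one-parameter sweeps over `g1`, `g2`, `g3`,
#' `g4`, `delta`; the `delta` sweep starts from the printed alternative
#' initial state).
#'
#' @param name Scenario name.
#' @return `list_scenarios()` returns the scenario names;
#'   `get_scenario()` the full scenario definition (parameters, initial
#'   states, fractional orders, doses/sweeps, horizon and step count).
#' @export
list_scenarios <- function() names(scenario_table())

#' @rdname list_scenarios
#' @export
get_scenario <- function(name) {
  tab <- scenario_table()
  if (!name %in% names(tab))
    stop("unknown scenario '", name, "'; registered: ",
         paste(names(tab), collapse = ", "))
  tab[[name]]
}

#' Run a registered scenario
#'
#' Integrates every sub-run of a scenario (one per fractional order,
#' initial state, dose triple or sweep value) with the PECE solver and
#' summarizes each run.  Horizon, step count, orders and other settings
#' can be overridden; `out_dir` writes one CSV per run.
#'
#' @param name Registered scenario name (see [list_scenarios()]).
#' @param alpha,t_end,n_steps Optional overrides of the registered values.
#' @param out_dir Optional directory for per-run CSV files
#'   (`<scenario>_<run>.csv`, header `t,T,M,G,C,P`).
#' @param quiet Suppress per-run log lines (default TRUE).
#' @return A list of runs; each run is a list with `label`, `traj`
#'   (`"caputo_traj"`) and `summary` (see [summarize_run()]).
#' @examples
#' \donttest{
#' runs <- run_scenario("app1_i", alpha = 0.9, t_end = 50, n_steps = 1000)
#' runs[[1]]$summary$terminal
#' }
#' @export
run_scenario <- function(name, alpha = NULL, t_end = NULL, n_steps = NULL,
                         out_dir = NULL, quiet = TRUE) {
  sc <- get_scenario(name)
  if (!is.null(t_end)) sc$t_end <- t_end
  if (!is.null(n_steps)) sc$n_steps <- as.integer(n_steps)
  if (!is.null(alpha)) sc$alphas <- alpha
  runs <- list()
  eq_ref <- scenario_equilibria(sc$params)
  for (a in sc$alphas) {
    if (!is.null(sc$doses)) {
      for (dn in seq_along(sc$doses)) {
        d <- sc$doses[[dn]]
        p <- modify_params(sc$params, list(u1 = d[1], u2 = d[2], u3 = d[3]))
        label <- sprintf("alpha%.2f_dose%d", a, dn)
        runs[[label]] <- one_run(sc, p, sc$initial[[1]], a, label,
                                 scenario_equilibria(p), quiet)
      }
    } else if (!is.null(sc$sweep)) {
      for (pname in names(sc$sweep)) {
        y0 <- sc$initial[[1]]
        if (!is.null(sc$sweep_initial[[pname]]))
          y0 <- sc$sweep_initial[[pname]]
        for (v in sc$sweep[[pname]]) {
          p <- modify_params(sc$params, setNames(list(v), pname))
          label <- sprintf("alpha%.2f_%s%.2f", a, pname, v)
          runs[[label]] <- one_run(sc, p, y0, a,
                                   label, scenario_equilibria(p), quiet)
        }
      }
    } else {
      for (i in seq_along(sc$initial)) {
        label <- if (length(sc$initial) > 1L)
          sprintf("alpha%.2f_init%d", a, i) else sprintf("alpha%.2f", a)
        runs[[label]] <- one_run(sc, sc$params, sc$initial[[i]], a, label,
                                 eq_ref, quiet)
      }
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (label in names(runs))
      write_trajectory_csv(runs[[label]]$traj,
                           file.path(out_dir, sprintf("%s_%s.csv", name, label)))
  }
  runs
}

modify_params <- function(params, changes) {
  pl <- unclass(params)
  pl[names(changes)] <- changes
  suppressWarnings(do.call(model_parameters, pl))
}

scenario_equilibria <- function(params) {
  co <- tryCatch(find_coexistence(params, scan_points = 2000L),
                 error = function(e) list())
  list(tumor_free = tryCatch(tumor_free_equilibrium(params),
                             error = function(e) NULL),
       coexistence = co)
}

one_run <- function(sc, params, y0, alpha, label, eq_ref, quiet) {
  t0 <- proc.time()[["elapsed"]]
  traj <- simulate_model(params, y0, alpha = alpha, t_end = sc$t_end,
                         n_steps = sc$n_steps, variant = sc$variant)
  undershoot <- min(traj$states)
  if (undershoot < -1e-6)
    warning(sprintf("run %s: component undershoot %.3g below -1e-6; treat as integration failure and rerun with a smaller step",
                    label, undershoot), call. = FALSE)
  sm <- summarize_run(traj, eq_ref)
  if (!quiet)
    message(sprintf("[%s] %s alpha=%.2f h=%.3g t_end=%g elapsed=%.2fs",
                    sc$name, label, alpha, traj$h, sc$t_end,
                    proc.time()[["elapsed"]] - t0))
  list(label = label, traj = traj, summary = sm)
}

#' Summarize one scenario run
#'
#' Computes the terminal state, per-component settling times (first time
#' after which the component stays within `eps` of its terminal value) and,
#' when reference equilibria are supplied, the nearest attractor
#' (tumor-free vs coexistence, by max-norm distance of the terminal state).
#'
#' @param traj A `"caputo_traj"` of the 5-state model.
#' @param equilibria Optional list with elements `tumor_free`
#'   (`"equilibrium_report"` or NULL) and `coexistence` (list of reports).
#' @param eps Settling band, default 0.1.
#' @return List with `terminal`, `settling_times`, `attractor`
#'   (`"tumor_free"`, `"coexistence"` or `NA`), `attractor_distance`,
#'   `min_state`.
#' @export
summarize_run <- function(traj, equilibria = NULL, eps = 0.1) {
  term <- terminal_state(traj)
  st <- vapply(colnames(traj$states), function(cp)
    time_to_threshold(traj, cp, term[[cp]], eps), 0)
  attractor <- NA_character_
  adist <- NA_real_
  if (!is.null(equilibria)) {
    cand <- list()
    if (!is.null(equilibria$tumor_free) && isTRUE(equilibria$tumor_free$exists))
      cand$tumor_free <- equilibria$tumor_free$state
    for (co in equilibria$coexistence)
      if (isTRUE(co$exists)) cand$coexistence <- co$state
    if (length(cand)) {
      d <- vapply(cand, function(s) max(abs(s - term)), 0)
      attractor <- names(which.min(d))
      adist <- min(d)
    }
  }
  list(terminal = term, settling_times = st, attractor = attractor,
       attractor_distance = adist, min_state = min(traj$states))
}

#' First time a component permanently enters a band
#'
#' Operationalizes "speed of approaching equilibrium": the first grid time
#' after which `|x_component - reference|` stays below `eps` through the end
#' of the trajectory.  `NA` if the band is never permanently entered;
#' treat `NA` as "slower than any finite time" when ordering runs.
#'
#' @param traj A `"caputo_traj"`.
#' @param component Column name (e.g. `"T"`) or index.
#' @param reference Reference level.
#' @param eps Band half-width (> 0).
#' @return Entry time (a grid point), or `NA_real_`.
#' @examples
#' sol <- solve_pece(function(y) -y, 1, 1, t_end = 10, n_steps = 100)
#' time_to_threshold(sol, 1, 0, 0.1)   # about log(10)
#' @export
time_to_threshold <- function(traj, component, reference, eps) {
  stopifnot(inherits(traj, "caputo_traj"), eps > 0)
  x <- traj$states[, component]
  inside <- abs(x - reference) < eps
  if (!inside[length(inside)]) return(NA_real_)
  bad <- which(!inside)
  if (!length(bad)) return(traj$times[1])
  traj$times[max(bad) + 1L]
}

#' Sweep one parameter of a scenario
#'
#' Re-runs a scenario's single-trajectory configuration once per value of
#' one model parameter and tabulates terminal states and tumor clearance
#' times.
#'
#' @param name Registered scenario name.
#' @param param A parameter name of [model_parameters()].
#' @param values Numeric vector of parameter values (may be empty).
#' @param alpha,t_end,n_steps Optional overrides.
#' @param clearance_level Tumor level defining clearance (default 0.1).
#' @param y0 Optional initial state override.
#' @return A data frame with one row per value: the swept value, terminal
#'   `T, M, G, C, P`, and `t_clear` (tumor clearance time, `NA` if not
#'   cleared on the horizon).
#' @examples
#' \donttest{
#' sweep_parameter("app3", "delta", c(0.15, 0.60), t_end = 50, n_steps = 1000)
#' }
#' @export
sweep_parameter <- function(name, param, values, alpha = NULL, t_end = NULL,
                            n_steps = NULL, clearance_level = 0.1, y0 = NULL) {
  sc <- get_scenario(name)
  if (!param %in% .param_names)
    stop("'", param, "' is not a model parameter")
  if (!is.numeric(values)) stop("sweep values must be numeric")
  if (!is.null(t_end)) sc$t_end <- t_end
  if (!is.null(n_steps)) sc$n_steps <- as.integer(n_steps)
  a <- if (!is.null(alpha)) alpha else sc$alphas[1]
  if (is.null(y0)) {
    y0 <- sc$initial[[1]]
    if (!is.null(sc$sweep_initial[[param]])) y0 <- sc$sweep_initial[[param]]
  }
  if (!length(values)) {
    out <- data.frame(value = numeric(0), T = numeric(0), M = numeric(0),
                      G = numeric(0), C = numeric(0), P = numeric(0),
                      t_clear = numeric(0), check.names = FALSE)
    names(out)[1] <- param
    return(out)
  }
  rows <- lapply(values, function(v) {
    p <- modify_params(sc$params, setNames(list(v), param))
    traj <- simulate_model(p, y0, alpha = a, t_end = sc$t_end,
                           n_steps = sc$n_steps, variant = sc$variant)
    term <- terminal_state(traj)
    data.frame(value = v, t(term),
               t_clear = time_to_threshold(traj, "T", 0, clearance_level))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  names(out)[1] <- param
  out
}
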