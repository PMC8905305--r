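#' Define a simulation scenario
#'
#' A scenario bundles the parameter set, initial state, time span and any
#' glucose-shutdown (clamp) windows. During a clamp window the external
#' glucose is held equal to the instantaneous internal concentration, which
#' removes the uptake gradient; this is implemented by switching to a vector
#' field with the uptake pathways zeroed, and the integrator is restarted at
#' window boundaries so the switching is sharp.
#'
#' @param params a [cone_parameters()] vector.
#' @param initial named state vector (see [cone_state()]).
#' @param t_span numeric length-2, start and end time in minutes.
#' @param clamp_windows `NULL`, or a list of numeric length-2 vectors
#'   `(t_on, t_off)`; windows must lie within `t_span`, be non-overlapping
#'   and have `t_on < t_off`.
#' @param label optional scenario identifier carried into exports.
#' @return an object of class `"cone_scenario"`.
#' @examples
#' sc <- cone_scenario(cone_parameters(G_E = 10, L_E = 9.4),
#'                     cone_state(G = 5, LACT = 9.4),
#'                     t_span = c(0, 240),
#'                     clamp_windows = list(c(40, 130)))
#' @export
cone_scenario <- function(params, initial, t_span = c(0, 240),
                          clamp_windows = NULL, label = "scenario") {
  validate_parameters(params)
  .check_state(initial)
  if (length(t_span) != 2 || t_span[2] <= t_span[1])
    stop("t_span must be an increasing length-2 vector")
  if (!is.null(clamp_windows)) {
    if (!is.list(clamp_windows)) clamp_windows <- list(clamp_windows)
    for (w in clamp_windows) {
      if (length(w) != 2 || w[1] > w[2])
        stop("clamp window must be (t_on, t_off) with t_on <= t_off")
      if (w[1] < t_span[1] || w[2] > t_span[2])
        stop("clamp window outside t_span")
    }
    if (length(clamp_windows) > 1) {
      o <- order(vapply(clamp_windows, `[`, 0, 1))
      clamp_windows <- clamp_windows[o]
      for (ii in seq_len(length(clamp_windows) - 1))
        if (clamp_windows[[ii]][2] > clamp_windows[[ii + 1]][1])
          stop("clamp windows overlap")
    }
  }
  structure(list(params = params,
                 initial = stats::setNames(as.numeric(initial), .state_names),
                 t_span = as.numeric(t_span),
                 clamp_windows = clamp_windows,
                 label = label),
            class = "cone_scenario")
}

#' @export
print.cone_scenario <- function(x, ...) {
  cat("cone scenario '", x$label, "': t = [", x$t_span[1], ", ", x$t_span[2],
      "] min, ", length(x$clamp_windows %||% list()),
      " glucose-shutdown window(s)\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split [t0, t1] into alternating free/clamped segments
.segments <- function(t_span, windows) {
  if (is.null(windows) || !length(windows))
    return(list(list(from = t_span[1], to = t_span[2], clamp = FALSE)))
  segs <- list()
  cur <- t_span[1]
  for (w in windows) {
    if (w[1] > cur)
      segs[[length(segs) + 1]] <- list(from = cur, to = w[1], clamp = FALSE)
    if (w[2] > w[1])
      segs[[length(segs) + 1]] <- list(from = w[1], to = w[2], clamp = TRUE)
    cur <- w[2]
  }
  if (cur < t_span[2])
    segs[[length(segs) + 1]] <- list(from = cur, to = t_span[2], clamp = FALSE)
  segs
}

#' Integrate a scenario
#'
#' Solves the model ODEs with a stiff-capable integrator (`deSolve::lsoda`,
#' rtol 1e-8 / atol 1e-10 by default), restarting at clamp-window edges.
#'
#' @param scenario a [cone_scenario()].
#' @param output_times numeric vector of report times within `t_span`;
#'   defaults to a 1-minute grid.
#' @param rtol,atol solver tolerances.
#' @return an object of class `"cone_trajectory"`: a list with `time`
#'   (minutes), `state` (matrix, one row per time point, columns G, G3P,
#'   PYR, LACT, ACoA, CIT) and the generating `scenario`.
#' @examples
#' sc <- cone_scenario(cone_parameters(), cone_state(G = 2, LACT = 9.4),
#'                     t_span = c(0, 60))
#' tr <- integrate_scenario(sc)
#' tail(as.data.frame(tr))
#' @export
integrate_scenario <- function(scenario, output_times = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(scenario, "cone_scenario"))
  ts <- scenario$t_span
  if (is.null(output_times))
    output_times <- seq(ts[1], ts[2], by = 1)
  output_times <- sort(unique(as.numeric(output_times)))
  if (min(output_times) < ts[1] || max(output_times) > ts[2])
    stop("output_times outside t_span")
  segs <- .segments(ts, scenario$clamp_windows)
  y <- scenario$initial
  times <- numeric(0)
  states <- NULL
  for (sg in segs) {
    tt <- output_times[output_times >= sg$from & output_times <= sg$to]
    tt <- sort(unique(c(sg$from, tt, sg$to)))
    f <- .rhs_fun(scenario$params, clamp = sg$clamp)
    sol <- deSolve::ode(y = y, times = tt, func = f, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("integration failed at t = %.3f min (state: %s)",
                   utils::tail(sol[, 1], 1),
                   paste(signif(utils::tail(sol, 1)[-1], 4), collapse = ", ")))
    y <- as.numeric(sol[nrow(sol), -1])
    names(y) <- .state_names
    keep <- sol[, 1] %in% output_times & !(sol[, 1] %in% times)
    times <- c(times, sol[keep, 1])
    states <- rbind(states, sol[keep, -1, drop = FALSE])
  }
  neg_tol <- -max(1e-9, 100 * atol)
  if (min(states) < neg_tol)
    warning("trajectory dips below ", signif(neg_tol, 2),
            " mM; solver tolerances may be too loose")
  states[states < 0] <- 0
  colnames(states) <- .state_names
  structure(list(time = times, state = states, scenario = scenario),
            class = "cone_trajectory")
}

#' @export
print.cone_trajectory <- function(x, ...) {
  cat("cone trajectory: ", length(x$time), " time points over [",
      min(x$time), ", ", max(x$time), "] min\n", sep = "")
  print(utils::tail(as.data.frame(x), 3))
  invisible(x)
}

#' @export
as.data.frame.cone_trajectory <- function(x, ...) {
  data.frame(time_min = x$time, x$state,
             scenario_id = x$scenario$label,
             stringsAsFactors = FALSE)
}

#' Export a trajectory as tidy CSV
#'
#' Columns: `time_min`, the six metabolites, `scenario_id`.
#'
#' @param trajectory a `cone_trajectory`.
#' @param file output path.
#' @export
write_trajectory <- function(trajectory, file) {
  utils::write.csv(as.data.frame(trajectory), file, row.names = FALSE)
  invisible(file)
}

#' Glucose-deprivation experiments with exogenous-fuel rescue
#'
#' Reproduces the reference starvation set-up: external and initial internal
#' glucose at very low levels, the uptake gradient clamped away for the whole
#' 0-120 min window, external lactate set so that no inward lactate gradient
#' exists, and no initial G3P. Variants add one rescue lever each:
#' `"g3p_boost"` starts with 2 mM G3P (fuelling beta-HB-derived acetyl-CoA);
#' `"lactate_boost"` raises external lactate to 9.92 mM (fuelling
#' lactate-derived pyruvate).
#'
#' @param variant one of `"baseline_starved"`, `"g3p_boost"`,
#'   `"lactate_boost"`.
#' @param t_end end of the simulated window (min).
#' @param output_times optional report grid.
#' @return a `cone_trajectory`.
#' @examples
#' tr <- run_deprivation_experiment("baseline_starved")
#' as.data.frame(tr)[51, c("time_min", "ACoA", "CIT")]
#' @export
run_deprivation_experiment <- function(variant = c("baseline_starved",
                                                   "g3p_boost",
                                                   "lactate_boost"),
                                       t_end = 120, output_times = NULL) {
  variant <- match.arg(variant)
  params <- cone_parameters(L_E = if (variant == "lactate_boost") 9.92 else 9.4)
  init <- cone_state(G = 0.5,
                     G3P = if (variant == "g3p_boost") 2 else 0,
                     LACT = 9.4)
  sc <- cone_scenario(params, init, t_span = c(0, t_end),
                      clamp_windows = list(c(0, t_end)),
                      label = paste0("deprivation_", variant))
  integrate_scenario(sc, output_times)
}

#' Glucose-shutdown experiments
#'
#' Base conditions: `G_E = 10`, `L_E = 9.4`, initial state `G = 5`,
#' `LACT = 9.4`, all other components zero, remaining parameters nominal.
#' Glucose uptake is prevented either never (`shutdown = "none"`), for the
#' whole simulation (`"full"`), or during a window (default 40-130 min).
#'
#' @param alpha G3P utilisation / fatty-acid oxidation rate (/min).
#' @param lambda_ GLUT1 efficiency.
#' @param shutdown `"none"`, `"full"`, or a numeric `(t_on, t_off)` window.
#' @param t_end simulation end (min); long horizons let slow recoveries
#'   complete.
#' @param output_times optional report grid.
#' @return a `cone_trajectory`.
#' @examples
#' tr <- run_shutdown_experiment(alpha = 0.18, shutdown = c(40, 130),
#'                               t_end = 400)
#' @export
run_shutdown_experiment <- function(alpha = 0.1, lambda_ = 0.0755,
                                    shutdown = c(40, 130),
                                    t_end = 2000, output_times = NULL) {
  params <- cone_parameters(alpha = alpha, lambda = lambda_,
                            G_E = 10, L_E = 9.4)
  wins <- if (identical(shutdown, "none")) NULL
          else if (identical(shutdown, "full")) list(c(0, t_end))
          else list(as.numeric(shutdown))
  sc <- cone_scenario(params, cone_state(G = 5, LACT = 9.4),
                      t_span = c(0, t_end), clamp_windows = wins,
                      label = sprintf("shutdown_a%g_l%g", alpha, lambda_))
  integrate_scenario(sc, output_times)
}

#' Classify the long-run outcome of a trajectory
#'
#' Labels a trajectory `"healthy"` or `"pathological"` according to the
#' stable equilibrium whose basin its final state lies in: integration is
#' continued from the final state until the solution comes within
#' `tol` (max-norm, mM) of one of the supplied stable equilibria, up to an
#' extension horizon; `"undecided"` is returned if neither is approached.
#'
#' @param trajectory a `cone_trajectory`, or a bare state vector.
#' @param equilibria a list of equilibrium points from [find_equilibria()]
#'   (unstable ones are ignored); each must carry a `label`
#'   (see [label_branches()] / [find_equilibria()]).
#' @param params parameters used for the continued integration; defaults to
#'   the trajectory's scenario parameters.
#' @param tol distance tolerance in mM (max norm).
#' @param horizon extension horizon in minutes.
#' @return one of `"healthy"`, `"pathological"`, `"undecided"`.
#' @export
classify_outcome <- function(trajectory, equilibria, params = NULL,
                             tol = 1e-3, horizon = 2000) {
  if (inherits(trajectory, "cone_trajectory")) {
    y <- trajectory$state[nrow(trajectory$state), ]
    params <- params %||% trajectory$scenario$params
  } else {
    y <- .check_state(trajectory)
    if (is.null(params)) stop("params required when classifying a bare state")
  }
  stable <- Filter(function(e) isTRUE(e$stable), equilibria)
  if (!length(stable))
    stop("no stable equilibrium supplied")
  f <- .rhs_fun(params)
  t0 <- 0
  step <- 250
  while (t0 < horizon) {
    near <- vapply(stable, function(e) max(abs(y - e$state)), 0)
    if (any(near < tol))
      return(stable[[which.min(near)]]$label)
    sol <- deSolve::ode(y = y, times = c(t0, t0 + step), func = f,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10)
    y <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    names(y) <- .state_names
    t0 <- t0 + step
  }
  near <- vapply(stable, function(e) max(abs(y - e$state)), 0)
  if (any(near < tol)) stable[[which.min(near)]]$label else "undecided"
}
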