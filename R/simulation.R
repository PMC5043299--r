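# Time integration of the full 5-state system, via deSolve.

#' Integrate the model
#'
#' Adaptive integration of [rhs_full()] with `deSolve::ode` (lsoda). The
#' capture denominator is checked along the trajectory; a crossing to
#' non-positive values aborts with the offending time. Population blow-up
#' beyond 1e3 times the natural scales is likewise reported.
#'
#' @param initial named 5-vector `(Sg, Ig, Sp, Ip, Z)` inside the invariant
#'   region (`0 <= Sg, Ig <= K`, `Sp + Ip = P`, `Z >= 0`).
#' @param params a `gang_params` object.
#' @param t_end final time.
#' @param times optional explicit output times (default 501 equally spaced
#'   points on `[0, t_end]`).
#' @param rel_tol,abs_tol solver tolerances (defaults 1e-8 / 1e-10).
#' @return A `gang_series`: data.frame with columns `time, Sg, Ig, Sp, Ip, Z`
#'   plus attributes `params` and `solver_meta`.
#' @export
#' @examples
#' ts <- simulate_model(c(Sg = 100, Ig = 10, Sp = 300, Ip = 0, Z = 0),
#'                      default_parameters(), t_end = 50)
#' tail(ts, 1)
simulate_model <- function(initial, params, t_end, times = NULL,
                           rel_tol = 1e-8, abs_tol = 1e-10) {
  stop_if_invalid(params)
  y0 <- as_full_state(initial)
  if (any(y0 < 0)) stop("initial state must be non-negative")
  capture_denominator(y0[["Sg"]], y0[["Ig"]], params)  # must start valid
  if (is.null(times)) times <- seq(0, t_end, length.out = 501)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  blow <- 1e3 * max(params$K, params$P)
  func <- function(t, y, parms) {
    if (any(!is.finite(y)) || max(abs(y)) > blow) {
      stop(sprintf("trajectory blow-up detected at t = %.6g", t))
    }
    if (min(y) < -1e-6 * (1 + max(abs(y)))) {
      stop(sprintf("trajectory left the region G at t = %.6g", t))
    }
    y <- pmax(y, 0)  # absorb the integrator's sub-tolerance undershoots
    h <- params$a * params$t_h
    D <- 1 + h * (y[1] + params$lam * y[2]) - params$c * params$P
    if (D <= 0) {
      stop(sprintf("capture denominator became nonpositive at t = %.6g", t))
    }
    list(rhs_full(y, params))
  }
  sol <- deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                      method = "lsoda", rtol = rel_tol, atol = abs_tol)
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  attr(out, "params") <- params
  attr(out, "solver_meta") <- list(rtol = rel_tol, atol = abs_tol,
                                   diagnostics = attributes(sol)$istate)
  class(out) <- c("gang_series", "data.frame")
  out
}

#' Plot a simulated time series
#'
#' Populations against time on one panel (log-free), one line per
#' compartment.
#'
#' @param x a `gang_series`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gang_series <- function(x, ...) {
  comps <- c("Sg", "Ig", "Sp", "Ip", "Z")
  graphics::matplot(x$time, as.matrix(x[comps]), type = "l", lty = 1,
                    xlab = "time", ylab = "population", ...)
  graphics::legend("topright", legend = comps, col = seq_along(comps),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Perturbation-relaxation experiment
#'
#' Displaces an equilibrium by `delta` in every component (or by a signed
#' per-component vector) and integrates; the equilibrium is declared
#' recovered when every component of the final state is within
#' `1e-3 * (1 + |component|)` of the equilibrium value.
#'
#' @param equilibrium an `equilibrium_record`.
#' @param delta scalar perturbation, or named 5-vector of signed
#'   perturbations.
#' @param params a `gang_params` object.
#' @param t_end integration horizon (default 5000).
#' @return List `returned` (logical), `final_distance` (per component),
#'   `series` (the `gang_series`).
#' @export
#' @examples
#' eq <- equilibrium_E4(default_parameters())[[1]]
#' perturbation_experiment(eq, 1e-4, default_parameters(), t_end = 500)$returned
perturbation_experiment <- function(equilibrium, delta, params,
                                    t_end = 5000) {
  if (!equilibrium$admissible) stop("equilibrium is not admissible")
  y_star <- equilibrium$state
  d <- if (length(delta) == 1) rep(delta, 5) else as_full_state(delta)
  y0 <- pmax(y_star + d, 0)
  series <- simulate_model(y0, params, t_end)
  final <- unlist(utils::tail(series, 1)[full_names])
  dist <- abs(final - y_star)
  list(returned = all(dist < 1e-3 * (1 + abs(y_star))),
       final_distance = dist, series = series)
}

#' Label the regime a trajectory settles into
#'
#' Compares a trajectory's final state with a set of candidate equilibria
#' and returns the label of the nearest one, provided every component is
#' within `tol * (1 + |component|)`; otherwise `"undetermined"` (e.g. when
#' `t_end` was too short).
#'
#' @param series a `gang_series`.
#' @param candidates list of `equilibrium_record`s.
#' @param tol relative matching tolerance (default 1e-2).
#' @return A label string or `"undetermined"`.
#' @export
regime_from_trajectory <- function(series, candidates, tol = 1e-2) {
  final <- unlist(utils::tail(series, 1)[full_names])
  best <- "undetermined"
  best_d <- Inf
  for (r in candidates) {
    if (!r$admissible) next
    rel <- abs(final - r$state) / (1 + abs(r$state))
    d <- max(rel)
    if (d < tol && d < best_d) {
      best <- r$label
      best_d <- d
    }
  }
  best
}
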