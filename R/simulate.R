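# episode durations must sit on the integration grid, otherwise the RK4
# stage sampling of the rectangular drive becomes inconsistent
steps_on_grid <- function(duration, dt, what) {
  n <- round(duration / dt)
  if (abs(n * dt - duration) > 1e-9 * max(1, duration))
    stop(what, " (= ", duration, ") must be an integer multiple of dt (= ", dt, ")")
  n
}

protocol_steps <- function(protocol, dt) {
  n_on <- steps_on_grid(protocol$t_on, dt, "t_on")
  n_off <- if (protocol$t_off > 0) steps_on_grid(protocol$t_off, dt, "t_off") else 0L
  if (n_on < 1) stop("t_on must be at least one integration step")
  list(n_on = n_on, n_off = n_off)
}

#' One classical RK4 step
#'
#' Advances the state by one step of the classical fourth-order Runge-Kutta
#' scheme, sampling the drive at the stage times `t`, `t + dt/2`,
#' `t + dt/2`, `t + dt` via [stimulus_at()].
#'
#' @inheritParams drift
#' @param t current time.
#' @param dt step size (> 0).
#' @param protocol a [stimulus_protocol()], or `NULL` for zero drive.
#' @return the state after one step.
#' @export
rk4_step <- function(model, state, t, dt, protocol = NULL) {
  stopifnot(dt > 0)
  s <- check_state(state)
  Iat <- function(tt) if (is.null(protocol)) 0 else stimulus_at(protocol, tt)
  k1 <- drift(model, s, Iat(t))
  k2 <- drift(model, s + dt / 2 * k1, Iat(t + dt / 2))
  k3 <- drift(model, s + dt / 2 * k2, Iat(t + dt / 2))
  k4 <- drift(model, s + dt * k3, Iat(t + dt))
  unname(s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
}

#' Integrate the model under a stimulation protocol
#'
#' Fixed-step RK4 integration (default `dt = 0.01`, in units of
#' \eqn{\tau_w}) from an initial state, recording the full trajectory and
#' the drive applied at each step. Fully deterministic.
#'
#' @inheritParams rk4_step
#' @param init initial state `c(w, z)`.
#' @param t_max end time (> 0).
#' @return object of class `consol_trajectory`: a data frame with columns
#'   `t`, `w`, `z`, `I`.
#' @export
integrate_model <- function(model, init, protocol = NULL, t_max, dt = 0.01) {
  stopifnot(inherits(model, "consol_model"), t_max > 0, dt > 0)
  s <- check_state(init)
  if (is.null(protocol)) protocol <- stimulus_protocol(0, t_on = dt)
  ps <- protocol_steps(protocol, dt)
  n_steps <- round(t_max / dt)
  n_eps <- if (is.infinite(protocol$n_episodes)) -1 else protocol$n_episodes
  tr <- rk4_traj_cpp(s[1], s[2], par_vec(model), protocol$amplitude,
                     ps$n_on, ps$n_off, n_eps, dt, n_steps)
  out <- data.frame(t = tr[, 1], w = tr[, 2], z = tr[, 3], I = tr[, 4])
  structure(out, class = c("consol_trajectory", "data.frame"),
            dt = dt, protocol = protocol)
}

#' @export
#' @method simulate consol_model
#' @rdname integrate_model
#' @param object a `consol_model` (generic-compatible alias for `model`).
#' @param nsim,seed ignored; the dynamics are deterministic.
#' @param ... passed on to [integrate_model()].
simulate.consol_model <- function(object, nsim = 1, seed = NULL, init, protocol = NULL,
                                  t_max, dt = 0.01, ...) {
  integrate_model(object, init = init, protocol = protocol, t_max = t_max, dt = dt)
}

#' @export
plot.consol_trajectory <- function(x, type = c("phase", "time"), ...) {
  type <- match.arg(type)
  if (type == "phase") {
    plot(x$w, x$z, type = "l", xlab = "w", ylab = "z", ...)
    points(x$w[1], x$z[1], pch = 19)
  } else {
    plot(x$t, x$w, type = "l", xlab = "t (units of tau_w)", ylab = "state", ...)
    lines(x$t, x$z, lty = 2)
    legend("bottomright", bty = "n", lty = 1:2, legend = c("w", "z"))
  }
  invisible(x)
}

#' Deliver episodes until the synapse potentiates
#'
#' Starts the system in the unpotentiated state \eqn{(-w_0, -z_0)} and
#' applies the protocol, testing after every integration step whether the
#' trajectory has entered the basin of attraction of the potentiated state
#' \eqn{(w_0, z_0)} (the basin of the drive-free phase portrait). On
#' crossing, the run stops; the episode count includes the episode during
#' which the crossing happened. If the episode budget is exhausted
#' mid-approach, a drive-free relaxation decides the outcome. The fast
#' membership test uses a precomputed separatrix ([separatrix_curve()]),
#' whose bisection construction shares the relaxation semantics of
#' [in_basin()].
#'
#' A DC protocol (`t_off = 0`, unbounded episodes) is integrated as one
#' sustained episode of duration `t_max` before the relaxation decision.
#'
#' @inheritParams integrate_model
#' @param max_episodes episode budget (cap also applied to finite
#'   `n_episodes`).
#' @param sep optional precomputed [separatrix_curve()] for this model and
#'   `dt` (computed on the fly if missing).
#' @param t_max time horizon for the DC limit and the deciding relaxation.
#' @param conv_tol convergence distance to an attractor.
#' @return object of class `consol_outcome`: `potentiated`,
#'   `episodes_delivered`, `crossing_time` (`NA` if never), `final_state`,
#'   `area` (delivered stimulus area when potentiated, else `NA`).
#' @examples
#' \donttest{
#' m <- consolidation_model(tau_z = 7)
#' run_until_potentiated(m, stimulus_protocol(17.75, 0.01, 0.11))
#' }
#' @export
run_until_potentiated <- function(model, protocol, max_episodes = 500,
                                  dt = 0.01, sep = NULL, t_max = NULL,
                                  conv_tol = 1e-3) {
  stopifnot(inherits(model, "consol_model"), inherits(protocol, "consol_protocol"))
  if (protocol$amplitude < 0)
    stop("protocol amplitude must be nonnegative for potentiation runs")
  if (is.null(t_max)) t_max <- 200 * max(model$tau_w, model$tau_z)
  att <- stable_attractors(model, input = 0)
  upper_idx <- which(sqrt((att$w - model$w0)^2 + (att$z - model$z0)^2) < 1e-6)
  if (length(upper_idx) != 1)
    stop("no potentiated stable fixed point (w0, z0) at I = 0")
  if (is.null(sep)) sep <- separatrix_curve(model, dt = dt, conv_tol = conv_tol)

  dc <- (protocol$t_off == 0 && is.infinite(protocol$n_episodes))
  if (dc) {
    n_on <- round(t_max / dt); n_off <- 0L; maxep <- 1
  } else {
    ps <- protocol_steps(protocol, dt)
    n_on <- ps$n_on; n_off <- ps$n_off
    maxep <- min(max_episodes, protocol$n_episodes)
  }
  res <- run_protocol_cpp(par_vec(model), protocol$amplitude, n_on, n_off,
                          maxep, dt, sep$w, sep$z,
                          as.matrix(att[, c("w", "z")]), upper_idx,
                          conv_tol, t_max, 1e-12)
  episodes <- as.integer(res$episodes)
  structure(list(potentiated = res$potentiated,
                 episodes_delivered = episodes,
                 crossing_time = res$crossing_time,
                 final_state = c(w = res$w, z = res$z),
                 area = if (res$potentiated && !dc)
                          protocol_area(protocol, episodes) else NA_real_,
                 protocol = protocol, dt = dt),
            class = "consol_outcome")
}

#' @export
print.consol_outcome <- function(x, ...) {
  if (x$potentiated) {
    cat(sprintf("Potentiated after %d episode(s), crossing at t = %.4g%s\n",
                x$episodes_delivered, x$crossing_time,
                if (is.finite(x$area)) sprintf(" (stimulus area %.4g)", x$area) else ""))
  } else {
    cat(sprintf("Not potentiated within %d episode(s)\n", x$episodes_delivered))
  }
  cat(sprintf("  final state (%.4g, %.4g)\n", x$final_state[1], x$final_state[2]))
  invisible(x)
}

#' Export a trajectory or outcome
#'
#' `write_trajectory` writes `t, w, z, I` as CSV; `write_outcome` writes the
#' simulation outcome as JSON.
#'
#' @param x a `consol_trajectory` or `consol_outcome`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "consol_trajectory"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
write_outcome <- function(x, path) {
  stopifnot(inherits(x, "consol_outcome"))
  jsonlite::write_json(list(potentiated = x$potentiated,
                            episodes_delivered = x$episodes_delivered,
                            crossing_time = x$crossing_time,
                            final_state = as.list(x$final_state),
                            area = x$area),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
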