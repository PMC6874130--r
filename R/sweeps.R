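new_sweep <- function(axis1, values1, axis2, values2, potentiated, episodes,
                      area, fixed, flagged = NULL) {
  structure(list(axis1 = axis1, values1 = values1,
                 axis2 = axis2, values2 = values2,
                 potentiated = potentiated, episodes = episodes, area = area,
                 fixed = fixed, flagged = flagged),
            class = "consol_sweep")
}

#' @export
print.consol_sweep <- function(x, ...) {
  cat(sprintf("Protocol sweep: %s (%d values) x %s (%d values)\n",
              x$axis1, length(x$values1), x$axis2, length(x$values2)))
  n_pot <- sum(x$potentiated, na.rm = TRUE)
  cat(sprintf("  %d / %d cells potentiated\n", n_pot, length(x$potentiated)))
  if (!is.null(x$argmin))
    cat(sprintf("  minimal area %.4g at %s = %g, %s = %g (%d episodes)\n",
                x$argmin$area, x$axis1, x$argmin[[x$axis1]],
                x$axis2, x$argmin[[x$axis2]], x$argmin$episodes))
  invisible(x)
}

#' @export
plot.consol_sweep <- function(x, what = c("potentiated", "area", "episodes"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  storage.mode(m) <- "double"
  image(x$values1, x$values2, m, xlab = x$axis1, ylab = x$axis2,
        col = hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' @export
as.data.frame.consol_sweep <- function(x, ...) {
  df <- expand.grid(a1 = x$values1, a2 = x$values2, KEEP.OUT.ATTRS = FALSE)
  names(df) <- c(x$axis1, x$axis2)
  df$potentiated <- as.vector(x$potentiated)
  df$episodes <- as.vector(x$episodes)
  df$area <- as.vector(x$area)
  df
}

sweep_context <- function(model, dt, conv_tol = 1e-3) {
  att <- stable_attractors(model, input = 0)
  upper_idx <- which(sqrt((att$w - model$w0)^2 + (att$z - model$z0)^2) < 1e-6)
  if (length(upper_idx) != 1)
    stop("no potentiated stable fixed point (w0, z0) at I = 0")
  list(att = as.matrix(att[, c("w", "z")]), upper_idx = upper_idx,
       sep = separatrix_curve(model, dt = dt, conv_tol = conv_tol),
       t_max = 200 * max(model$tau_w, model$tau_z), conv_tol = conv_tol)
}

run_cell <- function(model, ctx, amplitude, n_on, n_off, maxep, dt) {
  run_protocol_cpp(par_vec(model), amplitude, n_on, n_off, maxep, dt,
                   ctx$sep$w, ctx$sep$z, ctx$att, ctx$upper_idx,
                   ctx$conv_tol, ctx$t_max, 1e-12)
}

#' Single-episode potentiation map (amplitude x duration)
#'
#' For every grid cell, the system starts in the unpotentiated state, one
#' rectangular episode of the given amplitude and duration is applied, and
#' the drive-free relaxation decides whether the synapse ends up
#' potentiated. Durations are snapped to the integration grid (multiples of
#' `dt`). Amplitudes below the DC fold ([critical_dc_amplitude()]) can never
#' potentiate; raising the amplitude shortens the needed duration.
#'
#' @inheritParams run_until_potentiated
#' @param amplitudes nonnegative, increasing amplitude grid.
#' @param t_ons positive, increasing duration grid.
#' @return a `consol_sweep` (axes `amplitude`, `t_on`).
#' @export
potentiation_map_single <- function(model, amplitudes, t_ons, dt = 0.01,
                                    conv_tol = 1e-3) {
  stopifnot(all(diff(amplitudes) > 0), all(diff(t_ons) > 0),
            all(t_ons > 0), all(amplitudes >= 0))
  ctx <- sweep_context(model, dt, conv_tol)
  n1 <- length(amplitudes); n2 <- length(t_ons)
  pot <- matrix(FALSE, n1, n2); eps <- matrix(NA_integer_, n1, n2)
  area <- matrix(NA_real_, n1, n2)
  for (j in seq_len(n2)) {
    n_on <- max(1L, round(t_ons[j] / dt))
    for (i in seq_len(n1)) {
      if (amplitudes[i] == 0) { pot[i, j] <- FALSE; next }
      res <- run_cell(model, ctx, amplitudes[i], n_on, 0L, 1, dt)
      pot[i, j] <- res$potentiated
      eps[i, j] <- 1L
      if (res$potentiated) area[i, j] <- amplitudes[i] * n_on * dt
    }
  }
  new_sweep("amplitude", amplitudes, "t_on", t_ons, pot, eps, area,
            fixed = list(model = model, dt = dt, n_episodes = 1))
}

#' Single-episode potentiation map (amplitude x area)
#'
#' As [potentiation_map_single()], but the second axis is the stimulus area;
#' the episode duration is derived as `t_on = area / amplitude` and snapped
#' to the integration grid. Cells whose derived duration falls below one
#' step are unevaluable (`NA`); cells where snapping changes the delivered
#' area by more than 1% are flagged. With timescale separation
#' (`tau_z > tau_w`) the critical area has an interior minimum in the
#' amplitude: beyond an optimal amplitude, ever-shorter episodes approach a
#' horizontal kick in the phase plane, which cannot cross a separatrix that
#' flattens for large `w`, so the required area grows again.
#'
#' @inheritParams potentiation_map_single
#' @param areas positive, increasing grid of stimulus areas.
#' @return a `consol_sweep` (axes `amplitude`, `area`).
#' @export
potentiation_map_area <- function(model, amplitudes, areas, dt = 0.01,
                                  conv_tol = 1e-3) {
  stopifnot(all(diff(amplitudes) > 0), all(diff(areas) > 0),
            all(amplitudes > 0), all(areas > 0))
  ctx <- sweep_context(model, dt, conv_tol)
  n1 <- length(amplitudes); n2 <- length(areas)
  pot <- matrix(NA, n1, n2); eps <- matrix(NA_integer_, n1, n2)
  area_out <- matrix(NA_real_, n1, n2); flagged <- matrix(FALSE, n1, n2)
  n_unev <- 0L
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      t_on <- areas[j] / amplitudes[i]
      n_on <- round(t_on / dt)
      if (n_on < 1) { n_unev <- n_unev + 1L; next }
      delivered <- amplitudes[i] * n_on * dt
      if (abs(delivered - areas[j]) > 0.01 * areas[j]) flagged[i, j] <- TRUE
      res <- run_cell(model, ctx, amplitudes[i], n_on, 0L, 1, dt)
      pot[i, j] <- res$potentiated
      eps[i, j] <- 1L
      if (res$potentiated) area_out[i, j] <- delivered
    }
  }
  if (n_unev > 0)
    message(n_unev, " cell(s) unevaluable (derived t_on < dt)")
  new_sweep("amplitude", amplitudes, "area", areas, pot, eps, area_out,
            fixed = list(model = model, dt = dt, n_episodes = 1),
            flagged = flagged)
}

#' Repeated-episode potentiation map (amplitude x t_off)
#'
#' Each cell runs [run_until_potentiated()] with fixed episode duration
#' `t_on` and the cell's amplitude and inter-episode interval. The column
#' `t_off = 0` is the DC limit. Non-potentiated cells record the episode cap.
#'
#' @inheritParams potentiation_map_single
#' @param t_offs nonnegative, increasing inter-episode intervals.
#' @param t_on fixed episode duration.
#' @param max_episodes episode budget per cell.
#' @return a `consol_sweep` (axes `amplitude`, `t_off`).
#' @export
potentiation_map_repeated <- function(model, amplitudes, t_offs, t_on,
                                      max_episodes = 500, dt = 0.01,
                                      conv_tol = 1e-3) {
  stopifnot(all(diff(amplitudes) > 0), all(diff(t_offs) > 0),
            all(amplitudes > 0), all(t_offs >= 0), t_on > 0)
  ctx <- sweep_context(model, dt, conv_tol)
  n_on <- steps_on_grid(t_on, dt, "t_on")
  n1 <- length(amplitudes); n2 <- length(t_offs)
  pot <- matrix(FALSE, n1, n2); eps <- matrix(NA_integer_, n1, n2)
  area <- matrix(NA_real_, n1, n2)
  for (j in seq_len(n2)) {
    dc <- (t_offs[j] == 0)
    n_off <- if (dc) 0L else steps_on_grid(t_offs[j], dt, "t_off")
    for (i in seq_len(n1)) {
      res <- if (dc)
        run_cell(model, ctx, amplitudes[i], round(ctx$t_max / dt), 0L, 1, dt)
      else
        run_cell(model, ctx, amplitudes[i], n_on, n_off, max_episodes, dt)
      pot[i, j] <- res$potentiated
      eps[i, j] <- as.integer(res$episodes)
      if (res$potentiated && !dc)
        area[i, j] <- res$episodes * amplitudes[i] * n_on * dt
    }
  }
  new_sweep("amplitude", amplitudes, "t_off", t_offs, pot, eps, area,
            fixed = list(model = model, dt = dt, t_on = t_on,
                         max_episodes = max_episodes))
}

#' Minimal-stimulus-area search over repeated-episode protocols
#'
#' Sweeps amplitude and inter-episode interval for short repeated episodes
#' and locates the potentiated cell of minimal total stimulus area
#' (episodes x amplitude x t_on). The defaults target the strong
#' timescale-separation regime (`tau_z = 7 tau_w`, `t_on = 0.01 tau_w`) on
#' grids fine enough to resolve the optimum near amplitude 17.75 and
#' `t_off = 0.11`; ties break toward smaller amplitude, then smaller
#' `t_off`.
#'
#' @inheritParams potentiation_map_repeated
#' @return a `consol_sweep` with an extra `argmin` record (`amplitude`,
#'   `t_off`, `episodes`, `area`).
#' @export
minimal_area_search <- function(model = consolidation_model(tau_z = 7),
                                amplitudes = seq(5, 30, by = 0.25),
                                t_offs = seq(0.01, 1, by = 0.01),
                                t_on = 0.01, max_episodes = 500, dt = 0.01,
                                conv_tol = 1e-3) {
  sw <- potentiation_map_repeated(model, amplitudes, t_offs, t_on,
                                  max_episodes, dt, conv_tol)
  if (!any(sw$potentiated)) stop("no potentiated cell in the sweep")
  idx <- which(sw$potentiated, arr.ind = TRUE)
  areas <- sw$area[sw$potentiated]
  # ties toward smaller amplitude, then smaller t_off
  ord <- order(areas, sw$values1[idx[, 1]], sw$values2[idx[, 2]])
  best <- idx[ord[1], ]
  sw$argmin <- list(amplitude = sw$values1[best[1]],
                    t_off = sw$values2[best[2]],
                    episodes = sw$episodes[best[1], best[2]],
                    area = sw$area[best[1], best[2]])
  sw
}

#' Boundary between potentiating and non-potentiating protocols
#'
#' For each value on the sweep's first axis, interpolates the position of
#' the outcome change along the second axis (midpoint of the bracketing
#' grid values). Empty when the sweep contains a single outcome.
#'
#' @param sweep a `consol_sweep`.
#' @return data frame with the first-axis values and the interpolated
#'   critical second-axis value, ordered by the first axis.
#' @export
separation_curve <- function(sweep) {
  stopifnot(inherits(sweep, "consol_sweep"))
  out1 <- numeric(0); out2 <- numeric(0)
  for (i in seq_along(sweep$values1)) {
    row <- sweep$potentiated[i, ]
    ok <- !is.na(row)
    if (!any(row[ok]) || all(row[ok])) next
    flips <- which(diff(row[ok]) != 0)
    if (length(flips) == 0) next
    v2 <- sweep$values2[ok]
    j <- flips[1]
    out1 <- c(out1, sweep$values1[i])
    out2 <- c(out2, (v2[j] + v2[j + 1]) / 2)
  }
  df <- data.frame(a1 = out1, a2 = out2)
  names(df) <- c(sweep$axis1, paste0(sweep$axis2, "_critical"))
  df[order(df[[1]]), , drop = FALSE]
}

#' Export a sweep as CSV plus JSON metadata
#'
#' Long-format CSV (`axis1`, `axis2`, `potentiated`, `episodes`, `area`)
#' and a `<path>.json` sidecar with the fixed parameters, the grids and the
#' argmin record (when present).
#'
#' @param sweep a `consol_sweep`.
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "consol_sweep"))
  write.csv(as.data.frame(sweep), path, row.names = FALSE)
  fixed <- sweep$fixed
  meta <- list(model = unclass(fixed$model), dt = fixed$dt,
               t_on = fixed$t_on, n_episodes = fixed$n_episodes,
               max_episodes = fixed$max_episodes,
               axis1 = sweep$axis1, values1 = sweep$values1,
               axis2 = sweep$axis2, values2 = sweep$values2,
               argmin = sweep$argmin)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)], paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
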