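#' Bistable synaptic consolidation model
#'
#' Constructs the two-variable consolidation model: a fast synaptic weight
#' \eqn{w} (measurable efficacy, e.g. EPSP amplitude) and a slow
#' consolidation variable \eqn{z}, each with cubic bistable self-dynamics and
#' linear cross-coupling, driven by a plasticity-inducing stimulus \eqn{I(t)}
#' that enters the \eqn{w} equation only:
#' \deqn{\tau_w \dot w = -K_w (w - w_0)(w + w_0) w + C_w (z - \frac{z_0}{w_0} w) + I}
#' \deqn{\tau_z \dot z = -K_z (z - z_0)(z + z_0) z + C_z (w - \frac{w_0}{z_0} z)}
#' By construction \eqn{\pm(w_0, z_0)} are equilibria for \eqn{I = 0}
#' regardless of the couplings; they are interpreted as the potentiated and
#' unpotentiated synapse.
#'
#' Time is measured in units of \eqn{\tau_w}; the defaults (all parameters 1)
#' are the baseline used throughout the analyses in this package.
#'
#' @param C_w,C_z nonnegative coupling strengths into the \eqn{w} and
#'   \eqn{z} equations. Symmetric coupling means `C_w == C_z`.
#' @param K_w,K_z nonnegative cubic coefficients (0 makes the corresponding
#'   equation linear).
#' @param w0,z0 positive magnitudes of the stable equilibria.
#' @param tau_w,tau_z positive time constants; `tau_z >= tau_w` is the
#'   biologically relevant regime (consolidation slower than induction).
#' @return An object of class `consol_model`: a named list of the eight
#'   parameters.
#' @examples
#' m <- consolidation_model()
#' drift(m, c(1, 1))          # fixed point: zero velocity
#' find_fixed_points(m)
#' @export
consolidation_model <- function(C_w = 1, C_z = 1, K_w = 1, K_z = 1,
                                w0 = 1, z0 = 1, tau_w = 1, tau_z = 1) {
  m <- list(K_w = K_w, K_z = K_z, C_w = C_w, C_z = C_z,
            w0 = w0, z0 = z0, tau_w = tau_w, tau_z = tau_z)
  for (nm in names(m)) {
    v <- m[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (m$tau_w <= 0 || m$tau_z <= 0) stop("time constants must be positive")
  if (m$C_w < 0 || m$C_z < 0) stop("couplings C_w, C_z must be nonnegative")
  if (m$K_w < 0 || m$K_z < 0) stop("cubic coefficients K_w, K_z must be nonnegative")
  if (m$w0 <= 0 || m$z0 <= 0) stop("fixed-point magnitudes w0, z0 must be positive")
  structure(m, class = "consol_model")
}

# parameter vector in the fixed order used by the compiled core
par_vec <- function(model) {
  as.numeric(model[c("K_w", "K_z", "C_w", "C_z", "w0", "z0", "tau_w", "tau_z")])
}

check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 2L || any(!is.finite(state)))
    stop("state must be a finite numeric vector (w, z)")
  as.numeric(state)
}

#' @export
print.consol_model <- function(x, ...) {
  cat("Bistable synaptic consolidation model\n")
  cat(sprintf("  couplings:      C_w = %g, C_z = %g%s\n", x$C_w, x$C_z,
              if (x$C_w == x$C_z) "  (symmetric)" else ""))
  cat(sprintf("  cubic terms:    K_w = %g, K_z = %g\n", x$K_w, x$K_z))
  cat(sprintf("  equilibria at:  +/-(%g, %g)\n", x$w0, x$z0))
  cat(sprintf("  time constants: tau_w = %g, tau_z = %g (ratio %g)\n",
              x$tau_w, x$tau_z, x$tau_z / x$tau_w))
  invisible(x)
}

#' @export
summary.consol_model <- function(object, input = 0, ...) {
  fp <- find_fixed_points(object, input = input)
  out <- list(model = object, input = input, fixed_points = fp)
  class(out) <- "summary.consol_model"
  out
}

#' @export
print.summary.consol_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("\nFixed points at I = %g:\n", x$input))
  print(x$fixed_points)
  invisible(x)
}

#' Model vector field
#'
#' Time derivatives \eqn{(dw/dt, dz/dt)} of the consolidation model at a
#' state, for a given constant drive. The drive enters the \eqn{w} equation
#' only.
#'
#' @param model a [consolidation_model()].
#' @param state numeric `c(w, z)`.
#' @param input drive value \eqn{I} (dimensionless).
#' @return numeric `c(dw, dz)`.
#' @export
drift <- function(model, state, input = 0) {
  stopifnot(inherits(model, "consol_model"))
  s <- check_state(state)
  if (!is.numeric(input) || length(input) != 1L || !is.finite(input))
    stop("input must be a single finite number")
  w <- s[1]; z <- s[2]
  dw <- (-model$K_w * (w - model$w0) * (w + model$w0) * w +
           model$C_w * (z - model$z0 / model$w0 * w) + input) / model$tau_w
  dz <- (-model$K_z * (z - model$z0) * (z + model$z0) * z +
           model$C_z * (w - model$w0 / model$z0 * z)) / model$tau_z
  c(dw = dw, dz = dz)
}

#' Jacobian of the vector field
#'
#' Exact partial derivatives of [drift()] with respect to `(w, z)`,
#' including the \eqn{1/\tau} factors. Used for linear stability analysis.
#'
#' @inheritParams drift
#' @return a 2x2 numeric matrix.
#' @export
model_jacobian <- function(model, state) {
  stopifnot(inherits(model, "consol_model"))
  s <- check_state(state)
  w <- s[1]; z <- s[2]
  matrix(c(
    (-model$K_w * (3 * w^2 - model$w0^2) - model$C_w * model$z0 / model$w0) / model$tau_w,
    model$C_z / model$tau_z,
    model$C_w / model$tau_w,
    (-model$K_z * (3 * z^2 - model$z0^2) - model$C_z * model$w0 / model$z0) / model$tau_z
  ), nrow = 2)
}

#' Nullclines
#'
#' The \eqn{w}-nullcline expressed as \eqn{z} over \eqn{w} and the
#' \eqn{z}-nullcline expressed as \eqn{w} over \eqn{z}:
#' \deqn{z = \frac{z_0}{w_0} w + \frac{K_w}{C_w}(w - w_0)(w + w_0) w - \frac{I}{C_w}}
#' \deqn{w = \frac{w_0}{z_0} z + \frac{K_z}{C_z}(z - z_0)(z + z_0) z}
#' Equilibria are the nullcline intersections. A positive drive shifts the
#' \eqn{w}-nullcline downward, which shrinks the basin of the unpotentiated
#' state.
#'
#' @inheritParams drift
#' @param w,z coordinate values (vectorized).
#' @return the other coordinate on the nullcline.
#' @export
nullcline_w <- function(model, w, input = 0) {
  stopifnot(inherits(model, "consol_model"))
  if (model$C_w == 0)
    stop("degenerate nullcline: C_w = 0, the w-nullcline is not a graph over w")
  model$z0 / model$w0 * w +
    model$K_w / model$C_w * (w - model$w0) * (w + model$w0) * w -
    input / model$C_w
}

#' @rdname nullcline_w
#' @export
nullcline_z <- function(model, z) {
  stopifnot(inherits(model, "consol_model"))
  if (model$C_z == 0)
    stop("degenerate nullcline: C_z = 0, the z-nullcline is not a graph over z")
  model$w0 / model$z0 * z +
    model$K_z / model$C_z * (z - model$z0) * (z + model$z0) * z
}

#' Pseudopotential for symmetric coupling
#'
#' For symmetric coupling \eqn{C_w = C_z = C} the flow is the (negative,
#' \eqn{\tau}-scaled) gradient of
#' \deqn{V(w, z) = \frac{K_w}{4} w^4 + \frac{K_z}{4} z^4
#'   - \frac{K_w w_0^3 - z_0 C}{2 w_0} w^2
#'   - \frac{K_z z_0^3 - w_0 C}{2 z_0} z^2 - C w z - I w,}
#' i.e. \eqn{\tau_w \dot w = -\partial V/\partial w} and
#' \eqn{\tau_z \dot z = -\partial V/\partial z}, so \eqn{V} is non-increasing
#' along trajectories (a Lyapunov function for constant drive). The drive
#' contributes the tilt term \eqn{-I\,w}, whose negative \eqn{w}-derivative
#' is the additive drive \eqn{+I} in the \eqn{w} equation.
#'
#' @inheritParams drift
#' @return scalar \eqn{V(w, z)}.
#' @export
pseudopotential <- function(model, state, input = 0) {
  stopifnot(inherits(model, "consol_model"))
  if (model$C_w != model$C_z)
    stop("pseudopotential requires symmetric coupling (C_w == C_z)")
  s <- check_state(state)
  w <- s[1]; z <- s[2]; C <- model$C_w
  model$K_w / 4 * w^4 + model$K_z / 4 * z^4 -
    (model$K_w * model$w0^3 - model$z0 * C) / (2 * model$w0) * w^2 -
    (model$K_z * model$z0^3 - model$w0 * C) / (2 * model$z0) * z^2 -
    C * w * z - input * w
}

#' Read and write model parameters as a flat key-value file
#'
#' One `key = value` pair per line, keys `K_w, K_z, C_w, C_z, w0, z0,
#' tau_w, tau_z`. Values are written with full double precision so the
#' round-trip is lossless.
#'
#' @param model a [consolidation_model()].
#' @param path file path.
#' @return `read_model_params` returns a `consol_model`;
#'   `write_model_params` returns `path` invisibly.
#' @export
write_model_params <- function(model, path) {
  stopifnot(inherits(model, "consol_model"))
  lines <- sprintf("%s = %s", names(model),
                   vapply(model, function(v) formatC(v, digits = 17, format = "g"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), "")
  vals <- vapply(kv, function(x) as.numeric(trimws(x[2])), 0)
  expected <- c("K_w", "K_z", "C_w", "C_z", "w0", "z0", "tau_w", "tau_z")
  if (!setequal(keys, expected))
    stop("parameter file must contain exactly the keys: ",
         paste(expected, collapse = ", "))
  p <- as.list(setNames(vals, keys))
  consolidation_model(C_w = p$C_w, C_z = p$C_z, K_w = p$K_w, K_z = p$K_z,
                      w0 = p$w0, z0 = p$z0, tau_w = p$tau_w, tau_z = p$tau_z)
}

#' Phase-plane plot
#'
#' Draws the nullclines, the fixed points (filled: stable; open: unstable or
#' saddle) and optionally the separatrix of a model.
#'
#' @param x a `consol_model`.
#' @param input constant drive used for nullclines and equilibria.
#' @param bounds plotting range, used for both axes.
#' @param separatrix optional `consol_separatrix` to overlay.
#' @param ... passed to [plot()].
#' @export
plot.consol_model <- function(x, input = 0, bounds = c(-1.5, 1.5),
                              separatrix = NULL, ...) {
  ww <- seq(bounds[1], bounds[2], length.out = 400)
  plot(NA, xlim = bounds, ylim = bounds, xlab = "w (synaptic weight)",
       ylab = "z (consolidation)", ...)
  if (x$C_w > 0) lines(ww, nullcline_w(x, ww, input), col = "firebrick")
  if (x$C_z > 0) lines(nullcline_z(x, ww), ww, col = "steelblue")
  fp <- find_fixed_points(x, input = input)
  points(fp$w, fp$z, pch = ifelse(fp$classification == "stable", 19, 1), cex = 1.3)
  if (!is.null(separatrix))
    for (pl in separatrix$polylines) lines(pl$w, pl$z, col = "black", lwd = 2)
  legend("topleft", bty = "n", lty = 1, col = c("firebrick", "steelblue"),
         legend = c("w-nullcline", "z-nullcline"))
  invisible(x)
}
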