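with_couplings <- function(model, C_w, C_z) {
  consolidation_model(C_w = C_w, C_z = C_z, K_w = model$K_w, K_z = model$K_z,
                      w0 = model$w0, z0 = model$z0,
                      tau_w = model$tau_w, tau_z = model$tau_z)
}

#' Number of equilibria at given couplings
#'
#' Convenience wrapper around [find_fixed_points()]: the number of distinct
#' real equilibria of the model with couplings `(C_w, C_z)`. For
#' `C_w + C_z > 1` this is always 3 (no bifurcation is possible there); as
#' the couplings shrink the count rises through 5 to the maximum of 9.
#'
#' @param C_w,C_z nonnegative couplings.
#' @param model base model supplying the remaining parameters.
#' @param input constant drive.
#' @return integer count.
#' @export
count_fixed_points <- function(C_w, C_z, model = consolidation_model(),
                               input = 0) {
  nrow(find_fixed_points(with_couplings(model, C_w, C_z), input = input))
}

# bracket every change of an integer-valued count function over a coarse
# scan, then bisect each bracket; merge near-degenerate criticals
scan_bisect <- function(count_fun, lo, hi, step, tol, merge_tol = 1e-4) {
  xs <- seq(lo, hi, by = step)
  if (xs[length(xs)] < hi) xs <- c(xs, hi)
  counts <- vapply(xs, count_fun, 0L)
  crit <- numeric(0)
  for (i in seq_len(length(xs) - 1L)) {
    if (counts[i] != counts[i + 1]) {
      a <- xs[i]; b <- xs[i + 1]; ca <- counts[i]
      while (b - a > tol) {
        m <- (a + b) / 2
        if (count_fun(m) == ca) a <- m else b <- m
      }
      crit <- c(crit, (a + b) / 2)
    }
  }
  # report count-changes closer than merge_tol as a single critical value
  if (length(crit) > 1) {
    keep <- c(TRUE, diff(crit) > merge_tol)
    crit <- crit[keep]
  }
  crit
}

#' Pitchfork cascade of the symmetric model
#'
#' Sweeps the symmetric coupling \eqn{C_w = C_z = C} over a range, detects
#' every change in the number of equilibria on a coarse grid, and refines
#' each change point by bisection. For the baseline parameters the cascade
#' consists of a pitchfork at \eqn{C = 1/2} (the origin's second Jacobian
#' eigenvalue \eqn{1 - 2C} changes sign) and a degenerate pair of
#' pitchforks at \eqn{C = 1/3}. Bifurcations are detected by root-count
#' change, which is robust where eigenvalue tracking is delicate;
#' count-changes closer than `1e-4` are reported as one critical value.
#'
#' @param model base model (couplings are overridden by the sweep).
#' @param C_range numeric length 2, the swept interval.
#' @param tol bisection tolerance.
#' @param step coarse-scan step.
#' @param input constant drive.
#' @return numeric vector of critical couplings, in decreasing order.
#' @export
find_bifurcations_symmetric <- function(model = consolidation_model(),
                                        C_range = c(0.05, 1), tol = 1e-6,
                                        step = 0.01, input = 0) {
  if (length(C_range) != 2 || diff(C_range) <= 0)
    stop("C_range must be an increasing interval")
  crit <- scan_bisect(function(C) count_fixed_points(C, C, model, input),
                      C_range[1], C_range[2], step, tol)
  sort(crit, decreasing = TRUE)
}

#' Bifurcation boundary in the coupling plane
#'
#' For each supplied `C_w`, locates every critical `C_z` at which the
#' equilibrium count changes. The outermost boundary is the pitchfork of
#' the origin and satisfies \eqn{C_w + C_z = 1} (the determinant of the
#' origin Jacobian vanishes there); inner boundaries are found numerically.
#' Along an asymmetric cut (e.g. `C_w = 0.3`) three distinct bifurcations
#' occur as `C_z` decreases from 1 to 0.
#'
#' @inheritParams find_bifurcations_symmetric
#' @param C_w_values positive couplings at which to slice.
#' @param C_z_range swept interval in `C_z`.
#' @return named list (one entry per `C_w`) of critical `C_z` values in
#'   decreasing order.
#' @export
bifurcation_boundary <- function(model = consolidation_model(),
                                 C_w_values, C_z_range = c(0.01, 1.5),
                                 tol = 1e-6, step = 0.01, input = 0) {
  stopifnot(all(C_w_values > 0))
  out <- lapply(C_w_values, function(cw) {
    crit <- scan_bisect(function(cz) count_fixed_points(cw, cz, model, input),
                        C_z_range[1], C_z_range[2], step, tol)
    sort(crit, decreasing = TRUE)
  })
  names(out) <- formatC(C_w_values, format = "g")
  out
}

#' Critical DC drive (fold of the unpotentiated state)
#'
#' Under a constant positive drive the \eqn{w}-nullcline shifts downward;
#' at a critical amplitude the unpotentiated stable fixed point collides
#' with the saddle and disappears (a saddle-node), leaving the system
#' monostable so that any initial condition potentiates. This function
#' bisects on the drive for the loss of the stable fixed point on the
#' depressed side (`direction = +1`; `direction = -1` gives the mirror-image
#' loss of the potentiated state under negative drive, equal in magnitude
#' by odd symmetry).
#'
#' For the symmetric baseline (`C = 1`, `K = 1`, `w0 = z0 = 1`) the fold has
#' the closed form \eqn{I_c = 9^{-1/8} - 9^{-9/8} \approx 0.675}.
#'
#' @param model a [consolidation_model()] with three equilibria at `I = 0`.
#' @param direction `+1` (potentiating drive) or `-1`.
#' @param tol bisection tolerance on the drive.
#' @param I_hi upper end of the bisection bracket.
#' @return the signed critical drive.
#' @export
critical_dc_amplitude <- function(model = consolidation_model(),
                                  direction = 1, tol = 1e-6, I_hi = 10) {
  stopifnot(inherits(model, "consol_model"), direction %in% c(-1, 1))
  fp0 <- find_fixed_points(model, input = 0)
  if (nrow(fp0) < 3) stop("model must have at least three fixed points at I = 0")
  # does the attractor on the 'losing' side still exist at drive I?
  survives <- function(I) {
    fp <- find_fixed_points(model, input = direction * I)
    any(fp$classification == "stable" & direction * fp$w < 0)
  }
  if (!survives(0)) stop("no stable fixed point on the depressed side at I = 0")
  if (survives(I_hi)) stop("I_hi too small: no fold found in the bracket")
  a <- 0; b <- I_hi
  while (b - a > tol) {
    m <- (a + b) / 2
    if (survives(m)) a <- m else b <- m
  }
  direction * (a + b) / 2
}

#' One-parameter bifurcation diagram
#'
#' Tabulates all equilibria and their stability along a sweep of the
#' symmetric coupling (or of the drive), assigning branch identities by
#' nearest-continuation between consecutive parameter values.
#'
#' @inheritParams find_bifurcations_symmetric
#' @param parameter `"C"` (symmetric coupling) or `"I"` (drive).
#' @param values increasing parameter values.
#' @return object of class `consol_bifdiag`: data frame with columns
#'   `parameter`, `branch_id`, `w`, `z`, `classification`.
#' @export
bifurcation_diagram <- function(model = consolidation_model(),
                                parameter = c("C", "I"), values) {
  parameter <- match.arg(parameter)
  stopifnot(is.numeric(values), length(values) > 1)
  rows <- list()
  prev <- NULL
  next_id <- 1L
  for (v in values) {
    m <- if (parameter == "C") with_couplings(model, v, v) else model
    I <- if (parameter == "I") v else 0
    fp <- find_fixed_points(m, input = I)
    ids <- integer(nrow(fp))
    if (!is.null(prev) && nrow(prev) > 0 && nrow(fp) > 0) {
      used <- logical(nrow(prev))
      for (i in seq_len(nrow(fp))) {
        d <- sqrt((prev$w - fp$w[i])^2 + (prev$z - fp$z[i])^2)
        d[used] <- Inf
        j <- which.min(d)
        if (is.finite(d[j]) && d[j] < 0.5) {
          ids[i] <- prev$branch_id[j]; used[j] <- TRUE
        } else {
          ids[i] <- next_id; next_id <- next_id + 1L
        }
      }
    } else {
      ids <- seq_len(nrow(fp)) + next_id - 1L
      next_id <- next_id + nrow(fp)
    }
    if (nrow(fp) > 0)
      rows[[length(rows) + 1L]] <- data.frame(parameter = v, branch_id = ids,
                                              w = fp$w, z = fp$z,
                                              classification = fp$classification)
    prev <- if (nrow(fp) > 0) {
      tmp <- fp; tmp$branch_id <- ids; tmp
    } else NULL
  }
  structure(do.call(rbind, rows), class = c("consol_bifdiag", "data.frame"))
}

#' @export
plot.consol_bifdiag <- function(x, ...) {
  plot(x$parameter, x$w, type = "n", xlab = "parameter", ylab = "w", ...)
  for (b in unique(x$branch_id)) {
    sub <- x[x$branch_id == b, ]
    lines(sub$parameter, sub$w,
          lty = if (sub$classification[1] == "stable") 1 else 2)
  }
  invisible(x)
}
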