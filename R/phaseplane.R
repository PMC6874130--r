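# ---- small polynomial helpers (coefficient vectors, ascending powers) ----

polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

# q(p(x)) by Horner's scheme on the coefficients of q
polycompose <- function(q, p) {
  out <- q[length(q)]
  for (i in rev(seq_len(length(q) - 1L))) {
    out <- polymul(out, p)
    out[1] <- out[1] + q[i]
  }
  out
}

real_roots <- function(coef, im_tol = 1e-6) {
  # drop trailing (near-)zero leading coefficients
  while (length(coef) > 1 && coef[length(coef)] == 0) coef <- coef[-length(coef)]
  if (length(coef) <= 1) return(numeric(0))
  r <- polyroot(coef)
  Re(r[abs(Im(r)) < im_tol * pmax(1, abs(r))])
}

classify_eigenvalues <- function(ev, tol = 1e-9) {
  re <- Re(ev)
  if (any(abs(re) <= tol)) return("marginal")
  if (all(re < 0)) return("stable")
  if (all(re > 0)) return("unstable")
  "saddle"
}

# damped Newton polish of an equilibrium candidate on the full 2-D drift
newton_polish <- function(model, state, input, tol = 1e-12, max_iter = 100) {
  s <- state
  f <- drift(model, s, input)
  res <- max(abs(f))
  for (i in seq_len(max_iter)) {
    if (res < tol) return(s)
    J <- model_jacobian(model, s)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      s_new <- s - lambda * step
      f_new <- drift(model, s_new, input)
      if (max(abs(f_new)) < res || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    s <- s_new; f <- f_new; res <- max(abs(f))
  }
  if (res < tol) s else NULL
}

#' Find all equilibria of the model
#'
#' Substitutes the \eqn{w}-nullcline \eqn{z = P_3(w)} into the
#' \eqn{z}-nullcline \eqn{w = Q_3(z)}, yielding a univariate polynomial of
#' degree at most 9 whose real roots are the equilibrium \eqn{w}-values
#' (so the system has at most nine fixed points). Candidates are polished by
#' a damped Newton iteration on the full two-dimensional vector field and
#' deduplicated. When one coupling vanishes the system (partially)
#' decouples and the cubics are solved separately.
#'
#' @inheritParams drift
#' @param input constant drive \eqn{I}.
#' @return A data frame of class `consol_fixed_points` with columns `w`,
#'   `z`, `classification` (stable / saddle / unstable / marginal) and the
#'   two Jacobian `eigenvalues` (complex), sorted lexicographically by
#'   `(w, z)`.
#' @export
find_fixed_points <- function(model, input = 0) {
  stopifnot(inherits(model, "consol_model"))
  cand <- list()
  add <- function(w, z) cand[[length(cand) + 1L]] <<- c(w, z)

  if (model$C_w > 0 && model$C_z > 0) {
    P <- c(-input / model$C_w,
           model$z0 / model$w0 - model$K_w * model$w0^2 / model$C_w,
           0,
           model$K_w / model$C_w)
    Q <- c(0,
           model$w0 / model$z0 - model$K_z * model$z0^2 / model$C_z,
           0,
           model$K_z / model$C_z)
    comp <- polycompose(Q, P)      # Q(P(w))
    comp[2] <- comp[2] - 1         # Q(P(w)) - w = 0
    for (w in real_roots(comp)) {
      z <- P[1] + P[2] * w + P[4] * w^3
      add(w, z)
    }
  } else if (model$C_w == 0 && model$C_z > 0) {
    # w-equation closes on itself; z follows
    wc <- c(input, model$K_w * model$w0^2, 0, -model$K_w)
    ws <- real_roots(wc)
    if (model$K_w == 0) {
      if (input != 0) stop("no equilibria: C_w = 0, K_w = 0 and nonzero drive")
      stop("degenerate system: C_w = 0 and K_w = 0 leave w unconstrained")
    }
    for (w in ws) {
      zc <- c(model$C_z * w,
              model$K_z * model$z0^2 - model$C_z * model$w0 / model$z0,
              0, -model$K_z)
      for (z in real_roots(zc)) add(w, z)
    }
  } else if (model$C_w > 0 && model$C_z == 0) {
    if (model$K_z == 0)
      stop("degenerate system: C_z = 0 and K_z = 0 leave z unconstrained")
    zc <- c(0, model$K_z * model$z0^2, 0, -model$K_z)
    for (z in real_roots(zc)) {
      wc <- c(model$C_w * z + input,
              model$K_w * model$w0^2 - model$C_w * model$z0 / model$w0,
              0, -model$K_w)
      for (w in real_roots(wc)) add(w, z)
    }
  } else {
    # fully decoupled
    if (model$K_w == 0 || model$K_z == 0)
      stop("degenerate system: vanishing coupling and cubic coefficient")
    ws <- real_roots(c(input, model$K_w * model$w0^2, 0, -model$K_w))
    zs <- real_roots(c(0, model$K_z * model$z0^2, 0, -model$K_z))
    for (w in ws) for (z in zs) add(w, z)
  }

  polished <- list()
  for (s in cand) {
    p <- newton_polish(model, s, input)
    if (is.null(p)) {
      warning(sprintf("root polishing failed to converge near (%.4g, %.4g); candidate dropped",
                      s[1], s[2]))
      next
    }
    dup <- any(vapply(polished, function(q) max(abs(q - p)) < 1e-8, TRUE))
    if (!dup) polished[[length(polished) + 1L]] <- p
  }
  if (length(polished) == 0)
    return(structure(data.frame(w = numeric(0), z = numeric(0),
                                classification = character(0)),
                     class = c("consol_fixed_points", "data.frame")))

  fp <- do.call(rbind, polished)
  ord <- order(fp[, 1], fp[, 2])
  fp <- fp[ord, , drop = FALSE]
  eig <- t(apply(fp, 1, function(s) {
    ev <- eigen(model_jacobian(model, s), only.values = TRUE)$values
    ev[order(Re(ev), Im(ev))]
  }))
  out <- data.frame(w = fp[, 1], z = fp[, 2],
                    classification = apply(eig, 1, classify_eigenvalues),
                    row.names = NULL)
  out$eig1 <- eig[, 1]
  out$eig2 <- eig[, 2]
  structure(out, class = c("consol_fixed_points", "data.frame"))
}

#' Linear stability of an equilibrium
#'
#' Classifies an equilibrium by the eigenvalues of the Jacobian. The state
#' must actually be an equilibrium (drift max-norm below `1e-6`).
#' Eigenvalues with real part within `tol` of zero give the classification
#' `"marginal"` (as at exact bifurcation parameters) rather than a guess.
#'
#' @inheritParams drift
#' @param tol tolerance on eigenvalue real parts for marginality.
#' @return list with `classification` and complex `eigenvalues`.
#' @export
classify_stability <- function(model, state, input = 0, tol = 1e-9) {
  s <- check_state(state)
  if (max(abs(drift(model, s, input))) >= 1e-6)
    stop("state is not an equilibrium (drift max-norm >= 1e-6)")
  ev <- eigen(model_jacobian(model, s), only.values = TRUE)$values
  ev <- ev[order(Re(ev), Im(ev))]
  list(classification = classify_eigenvalues(ev, tol), eigenvalues = ev)
}

stable_attractors <- function(model, input = 0) {
  fp <- find_fixed_points(model, input = input)
  fp[fp$classification == "stable", , drop = FALSE]
}

#' Basins of attraction by mesh-grid relaxation
#'
#' Initializes the model at every point of a regular grid and integrates
#' (RK4, constant drive) until the trajectory comes within `conv_tol` of a
#' stable fixed point, recording which one. Defaults follow the reference
#' setup: a 100 x 100 grid on \eqn{[-1.5, 1.5]^2} with `dt = 0.01`.
#'
#' @inheritParams drift
#' @param bounds numeric length 2, the common (w and z) grid range.
#' @param resolution grid points per axis.
#' @param dt integration step.
#' @param t_max maximum integration time per grid point; defaults to
#'   `200 * max(tau_w, tau_z)`.
#' @param conv_tol Euclidean convergence distance to an attractor.
#' @return object of class `consol_basins`: grid coordinates `w`, `z`, an
#'   integer `labels` matrix (index into `attractors`, 0 = non-convergent),
#'   the stable `attractors`, `drive`, and bookkeeping fields.
#' @export
compute_basins <- function(model, input = 0, bounds = c(-1.5, 1.5),
                           resolution = 100, dt = 0.01, t_max = NULL,
                           conv_tol = 1e-3) {
  stopifnot(inherits(model, "consol_model"))
  if (is.null(t_max)) t_max <- 200 * max(model$tau_w, model$tau_z)
  att <- stable_attractors(model, input = input)
  if (nrow(att) == 0) stop("no stable fixed point for this drive")
  ws <- seq(bounds[1], bounds[2], length.out = resolution)
  zs <- ws
  labels <- basin_labels_cpp(ws, zs, par_vec(model), input,
                             as.matrix(att[, c("w", "z")]), conv_tol, dt, t_max)
  n_nc <- sum(labels == 0L)
  if (n_nc > 0)
    message(n_nc, " grid cell(s) did not converge within t_max")
  structure(list(w = ws, z = zs, labels = labels,
                 attractors = att, bounds = bounds, resolution = resolution,
                 drive = input, dt = dt, t_max = t_max, conv_tol = conv_tol,
                 n_nonconvergent = n_nc, model = model),
            class = "consol_basins")
}

#' @export
print.consol_basins <- function(x, ...) {
  cat(sprintf("Basin map: %d x %d grid on [%g, %g]^2, drive I = %g\n",
              x$resolution, x$resolution, x$bounds[1], x$bounds[2], x$drive))
  cat(sprintf("  %d attractor(s); %d non-convergent cell(s)\n",
              nrow(x$attractors), x$n_nonconvergent))
  tab <- table(factor(x$labels, levels = 0:nrow(x$attractors)))
  for (i in seq_len(nrow(x$attractors)))
    cat(sprintf("  basin of (%.4g, %.4g): %d cells\n",
                x$attractors$w[i], x$attractors$z[i], tab[[as.character(i)]]))
  invisible(x)
}

#' @export
plot.consol_basins <- function(x, ...) {
  image(x$w, x$z, x$labels, col = hcl.colors(max(2, nrow(x$attractors)), "Set 2"),
        xlab = "w", ylab = "z", ...)
  points(x$attractors$w, x$attractors$z, pch = 19)
  invisible(x)
}

#' Extract the separatrix from a basin map
#'
#' Marks every edge between adjacent, differently-labelled grid cells with
#' its mid-edge point and chains the points of each label pair into ordered
#' polylines (the interpolated separation line of the mesh-grid method).
#'
#' @param basin_map a [compute_basins()] result.
#' @return object of class `consol_separatrix`: a list `polylines` of data
#'   frames with columns `w`, `z` (empty when the map has fewer than two
#'   attractors), plus the label `pairs` each polyline separates.
#' @export
extract_separatrix <- function(basin_map) {
  stopifnot(inherits(basin_map, "consol_basins"))
  L <- basin_map$labels
  ws <- basin_map$w; zs <- basin_map$z
  pts <- list(); pair <- character(0)
  push <- function(w, z, a, b) {
    pts[[length(pts) + 1L]] <<- c(w, z)
    pair[length(pair) + 1L] <<- paste(sort(c(a, b)), collapse = "-")
  }
  # boundary points between differently-labelled cells along each grid line;
  # narrow runs of non-convergent cells (trajectories trapped near the
  # saddle, i.e. cells sitting on the separatrix itself) are bridged
  scan_line <- function(lab, coord, fixed, horizontal) {
    idx <- which(lab > 0)
    for (k in seq_len(max(0, length(idx) - 1L))) {
      i1 <- idx[k]; i2 <- idx[k + 1]
      if (lab[i1] != lab[i2] && i2 - i1 <= 3) {
        mid <- (coord[i1] + coord[i2]) / 2
        if (horizontal) push(mid, fixed, lab[i1], lab[i2])
        else push(fixed, mid, lab[i1], lab[i2])
      }
    }
  }
  for (j in seq_along(zs)) scan_line(L[, j], ws, zs[j], TRUE)
  for (i in seq_along(ws)) scan_line(L[i, ], zs, ws[i], FALSE)
  polylines <- list(); pairs <- character(0)
  if (length(pts) > 0) {
    spacing <- ws[2] - ws[1]
    P <- do.call(rbind, pts)
    for (pr in unique(pair)) {
      sub <- P[pair == pr, , drop = FALSE]
      for (pl in chain_points(sub, spacing)) {
        polylines[[length(polylines) + 1L]] <- data.frame(w = pl[, 1], z = pl[, 2])
        pairs <- c(pairs, pr)
      }
    }
  }
  structure(list(polylines = polylines, pairs = pairs,
                 spacing = if (length(basin_map$w) > 1) basin_map$w[2] - basin_map$w[1] else NA_real_),
            class = "consol_separatrix")
}

# greedy nearest-neighbour chaining of boundary points into polylines
chain_points <- function(P, spacing) {
  n <- nrow(P)
  if (n == 0) return(list())
  D <- as.matrix(stats::dist(P))
  diag(D) <- Inf
  # prefer to start at an endpoint: a point with a single close neighbour
  close_counts <- rowSums(D < 1.5 * spacing)
  remaining <- rep(TRUE, n)
  out <- list()
  while (any(remaining)) {
    idx_rem <- which(remaining)
    start <- idx_rem[which.min(ifelse(close_counts[idx_rem] <= 1, 0, 1))]
    path <- start; remaining[start] <- FALSE
    cur <- start
    repeat {
      idx_rem <- which(remaining)
      if (length(idx_rem) == 0) break
      nxt <- idx_rem[which.min(D[cur, idx_rem])]
      if (D[cur, nxt] > 3 * spacing) break
      path <- c(path, nxt); remaining[nxt] <- FALSE; cur <- nxt
    }
    pl <- P[path, , drop = FALSE]
    keep <- c(TRUE, rowSums(abs(diff(pl))) > 0)
    out[[length(out) + 1L]] <- pl[keep, , drop = FALSE]
  }
  out
}

#' @export
print.consol_separatrix <- function(x, ...) {
  cat(sprintf("Separatrix: %d polyline(s)\n", length(x$polylines)))
  for (i in seq_along(x$polylines))
    cat(sprintf("  [%d] %d vertices, separates basins %s\n", i,
                nrow(x$polylines[[i]]), x$pairs[i]))
  invisible(x)
}

#' Basin membership of a state
#'
#' Reference semantics: integrate from `state` with zero drive until the
#' trajectory converges to a stable fixed point, and report whether that
#' limit is `target`. This is the stopping rule used when simulating
#' stimulation protocols (there the test is accelerated by a precomputed
#' separatrix, see [separatrix_curve()]).
#'
#' @inheritParams compute_basins
#' @param state numeric `c(w, z)` starting point.
#' @param target numeric `c(w, z)`, a stable equilibrium at `I = 0`.
#' @return `TRUE` or `FALSE`; non-convergence within `t_max` is an error.
#' @export
in_basin <- function(model, state, target, dt = 0.01, t_max = NULL,
                     conv_tol = 1e-3) {
  stopifnot(inherits(model, "consol_model"))
  s <- check_state(state)
  tg <- check_state(target)
  if (is.null(t_max)) t_max <- 200 * max(model$tau_w, model$tau_z)
  att <- stable_attractors(model, input = 0)
  if (nrow(att) == 0) stop("no stable fixed point at I = 0")
  d_tg <- sqrt((att$w - tg[1])^2 + (att$z - tg[2])^2)
  if (min(d_tg) > 1e-6) stop("target is not a stable fixed point at I = 0")
  res <- relax_cpp(s[1], s[2], par_vec(model), 0,
                   as.matrix(att[, c("w", "z")]), conv_tol, dt, t_max)
  if (res$label == 0)
    stop("indeterminate: trajectory did not converge within t_max")
  res$label == which.min(d_tg)
}

#' High-precision separatrix as a graph z = s(w)
#'
#' For each tabulated `w`, bisects in `z` between a point that relaxes to
#' the unpotentiated basin and one that relaxes to the potentiated basin,
#' using the same relaxation semantics as [in_basin()]. The result is a
#' lookup table used as the fast basin-membership test during protocol
#' simulation. Only valid when the phase portrait at `I = 0` is bistable
#' with a separatrix that is a graph over `w` (the baseline regime
#' `C_w + C_z > 1`).
#'
#' @inheritParams compute_basins
#' @param w_range range of `w` over which to tabulate.
#' @param n number of tabulation points.
#' @param z_bracket initial bisection bracket in `z`.
#' @param tol_z bisection tolerance on the separatrix height.
#' @return object of class `consol_sepcurve`: data frame columns `w`, `z`.
#' @export
separatrix_curve <- function(model, w_range = c(-3, 3), n = 161,
                             z_bracket = c(-4, 4), tol_z = 1e-8,
                             dt = 0.01, t_max = NULL, conv_tol = 1e-3) {
  stopifnot(inherits(model, "consol_model"))
  if (is.null(t_max)) t_max <- 200 * max(model$tau_w, model$tau_z)
  att <- stable_attractors(model, input = 0)
  if (nrow(att) < 2) stop("separatrix requires at least two stable fixed points")
  upper_idx <- which.min((att$w - model$w0)^2 + (att$z - model$z0)^2)
  ws <- seq(w_range[1], w_range[2], length.out = n)
  zs <- separatrix_bisect_cpp(ws, par_vec(model), z_bracket[1], z_bracket[2],
                              as.matrix(att[, c("w", "z")]), upper_idx,
                              tol_z, conv_tol, dt, t_max)
  ok <- is.finite(zs)
  if (!any(ok)) stop("separatrix bisection failed at every tabulated w")
  if (mean(ok) < 0.9)
    warning("separatrix bracket invalid at ", sum(!ok), " of ", n, " points")
  structure(data.frame(w = ws[ok], z = zs[ok]),
            class = c("consol_sepcurve", "data.frame"))
}

# fast membership of the potentiated basin via a tabulated separatrix
above_separatrix <- function(sep, w, z) {
  z > stats::approx(sep$w, sep$z, xout = w, rule = 2)$y
}

# ---- exports ----

#' Export phase-plane objects as plain-text files
#'
#' `write_basins` writes the label grid as long-format CSV (`w`, `z`,
#' `label`) plus a JSON metadata sidecar (attractors, bounds, resolution,
#' drive, non-convergent count). `write_separatrix` writes the polylines as
#' CSV (`polyline_id`, `order`, `w`, `z`).
#'
#' @param basins a `consol_basins`; `sep` a `consol_separatrix`.
#' @param path CSV output path; metadata goes to `<path>.json`.
#' @return the path, invisibly.
#' @export
write_basins <- function(basins, path) {
  stopifnot(inherits(basins, "consol_basins"))
  df <- expand.grid(w = basins$w, z = basins$z, KEEP.OUT.ATTRS = FALSE)
  df$label <- as.vector(basins$labels)
  write.csv(df, path, row.names = FALSE)
  meta <- list(attractors = basins$attractors[, c("w", "z")],
               bounds = basins$bounds, resolution = basins$resolution,
               drive = basins$drive,
               n_nonconvergent = basins$n_nonconvergent)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_basins
#' @param sep a `consol_separatrix`.
#' @export
write_separatrix <- function(sep, path) {
  stopifnot(inherits(sep, "consol_separatrix"))
  rows <- lapply(seq_along(sep$polylines), function(i) {
    pl <- sep$polylines[[i]]
    data.frame(polyline_id = i, order = seq_len(nrow(pl)), w = pl$w, z = pl$z)
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(polyline_id = integer(0), order = integer(0),
                        w = numeric(0), z = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
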