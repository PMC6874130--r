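# Independent oracles, deliberately separate from the package implementation.

# direct transcription of the model equations
oracle_drift <- function(m, w, z, I = 0) {
  c((-m$K_w * (w - m$w0) * (w + m$w0) * w + m$C_w * (z - m$z0 / m$w0 * w) + I) / m$tau_w,
    (-m$K_z * (z - m$z0) * (z + m$z0) * z + m$C_z * (w - m$w0 / m$z0 * z)) / m$tau_z)
}

central_diff <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(length(f(x))))
}

# brute-force equilibrium finder: scan a grid for cells where both drift
# components change sign, refine candidates by 2-D Newton with a
# finite-difference Jacobian
brute_fixed_points <- function(m, input = 0, bounds = c(-2, 2), n = 400) {
  g <- seq(bounds[1], bounds[2], length.out = n)
  W <- matrix(g, n, n)
  Z <- matrix(g, n, n, byrow = TRUE)
  F1 <- -m$K_w * (W - m$w0) * (W + m$w0) * W + m$C_w * (Z - m$z0 / m$w0 * W) + input
  F2 <- -m$K_z * (Z - m$z0) * (Z + m$z0) * Z + m$C_z * (W - m$w0 / m$z0 * Z)
  s1 <- sign(F1); s2 <- sign(F2)
  i <- seq_len(n - 1); j <- seq_len(n - 1)
  var1 <- (s1[i, j] != s1[i + 1, j]) | (s1[i, j] != s1[i, j + 1]) |
          (s1[i, j] != s1[i + 1, j + 1])
  var2 <- (s2[i, j] != s2[i + 1, j]) | (s2[i, j] != s2[i, j + 1]) |
          (s2[i, j] != s2[i + 1, j + 1])
  cand <- which(var1 & var2, arr.ind = TRUE)
  f <- function(s) oracle_drift(m, s[1], s[2], input)
  roots <- list()
  for (k in seq_len(nrow(cand))) {
    s <- c((g[cand[k, 1]] + g[cand[k, 1] + 1]) / 2,
           (g[cand[k, 2]] + g[cand[k, 2] + 1]) / 2)
    ok <- FALSE
    for (it in 1:60) {
      fv <- f(s)
      if (max(abs(fv)) < 1e-11) { ok <- TRUE; break }
      J <- central_diff(f, s, h = 1e-7)
      step <- tryCatch(solve(J, fv), error = function(e) NULL)
      if (is.null(step)) break
      s <- s - step
      if (max(abs(s)) > 10) break
    }
    if (!ok) next
    dup <- any(vapply(roots, function(r) max(abs(r - s)) < 1e-6, TRUE))
    if (!dup) roots[[length(roots) + 1L]] <- s
  }
  if (length(roots) == 0) return(matrix(numeric(0), ncol = 2))
  out <- do.call(rbind, roots)
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# trajectory under constant drive via deSolve (independent integrator)
desolve_traj <- function(m, init, input, t_end, dt) {
  f <- function(t, y, parms) list(oracle_drift(m, y[1], y[2], input))
  deSolve::ode(y = init, times = seq(0, t_end, by = dt), func = f,
               parms = NULL, method = "rk4")
}
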