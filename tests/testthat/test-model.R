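test_that("vector field matches hand-evaluated values and the oracle transcription", {
  m <- consolidation_model()
  expect_equal(unname(drift(m, c(1, 1))), c(0, 0))
  expect_equal(unname(drift(m, c(-1, -1))), c(0, 0))
  expect_equal(unname(drift(m, c(0, 0), input = 0.5)), c(0.5, 0))
  expect_equal(unname(drift(m, c(0.5, 0))), c(-0.125, 0.5))

  set.seed(11)
  for (k in 1:20) {
    p <- consolidation_model(C_w = runif(1, 0, 2), C_z = runif(1, 0, 2),
                             K_w = sample(0:1, 1), w0 = runif(1, 0.5, 2),
                             z0 = runif(1, 0.5, 2), tau_z = runif(1, 0.5, 8))
    s <- runif(2, -2, 2); I <- runif(1, -1, 1)
    expect_equal(unname(drift(p, s, I)), oracle_drift(p, s[1], s[2], I))
  }

  expect_error(drift(m, c(NaN, 0)), "finite")
  expect_error(drift(m, c(0, 0), input = Inf), "finite")
  expect_error(consolidation_model(tau_w = 0), "positive")
  expect_error(consolidation_model(C_w = -0.1), "nonnegative")
})

test_that("the two stable equilibria sit at +/-(w0, z0) for any valid parameters", {
  set.seed(21)
  for (k in 1:25) {
    p <- consolidation_model(C_w = runif(1, 0, 3), C_z = runif(1, 0, 3),
                             K_w = runif(1, 0, 2), K_z = runif(1, 0, 2),
                             w0 = runif(1, 0.2, 3), z0 = runif(1, 0.2, 3),
                             tau_w = runif(1, 0.1, 5), tau_z = runif(1, 0.1, 5))
    expect_lt(max(abs(drift(p, c(p$w0, p$z0)))), 1e-12)
    expect_lt(max(abs(drift(p, c(-p$w0, -p$z0)))), 1e-12)
  }
})

test_that("the flow has odd symmetry: negating state and drive negates the field", {
  set.seed(31)
  m <- consolidation_model(C_w = 0.7, C_z = 1.3, tau_z = 4)
  for (k in 1:30) {
    s <- runif(2, -2, 2); I <- runif(1, -2, 2)
    expect_equal(unname(drift(m, -s, -I)), -unname(drift(m, s, I)))
  }
})

test_that("the Jacobian is the exact linearization of the vector field", {
  m <- consolidation_model()
  J0 <- model_jacobian(m, c(0, 0))
  expect_equal(J0, matrix(c(0, 1, 1, 0), 2))
  expect_equal(sort(eigen(J0)$values), c(-1, 1))
  J1 <- model_jacobian(m, c(1, 1))
  expect_equal(J1, matrix(c(-3, 1, 1, -3), 2))
  expect_equal(sort(eigen(J1)$values), c(-4, -2))

  set.seed(41)
  p <- consolidation_model(C_w = 1.2, C_z = 0.4, K_z = 0.5, tau_z = 3,
                           w0 = 1.5, z0 = 0.8)
  for (k in 1:100) {
    s <- runif(2, -2, 2)
    fd <- central_diff(function(x) unname(drift(p, x)), s)
    expect_lt(max(abs(model_jacobian(p, s) - fd)), 1e-6)
  }
})

test_that("nullclines solve their drift component to round-off", {
  m <- consolidation_model()
  expect_equal(nullcline_w(m, 0), 0)
  expect_equal(nullcline_w(m, 1), 1)
  expect_equal(nullcline_w(m, 0.5), 0.125)
  expect_equal(nullcline_z(m, 0), 0)
  expect_equal(nullcline_z(m, -1), -1)
  expect_equal(nullcline_z(m, 0.5), 0.125)

  set.seed(51)
  p <- consolidation_model(C_w = 0.6, C_z = 1.7, K_z = 0, tau_z = 2)
  for (k in 1:25) {
    w <- runif(1, -2, 2); I <- runif(1, -1, 1)
    expect_lt(abs(drift(p, c(w, nullcline_w(p, w, I)), I)[1]), 1e-12)
    z <- runif(1, -2, 2)
    expect_lt(abs(drift(p, c(nullcline_z(p, z), z))[2]), 1e-12)
  }

  m0 <- consolidation_model(C_w = 0)
  expect_error(nullcline_w(m0, 1), "degenerate")
  expect_error(nullcline_z(consolidation_model(C_z = 0), 1), "degenerate")
})

test_that("the pseudopotential generates the flow and decreases along trajectories", {
  m <- consolidation_model()
  expect_equal(pseudopotential(m, c(0, 0)), 0)
  expect_equal(pseudopotential(m, c(1, 1)), -0.5)
  expect_error(pseudopotential(consolidation_model(C_w = 1, C_z = 0.5), c(0, 0)),
               "symmetric")

  # -grad V, scaled by tau, equals the vector field (drive included)
  set.seed(61)
  for (k in 1:100) {
    p <- consolidation_model(C_w = 0.8, C_z = 0.8, tau_z = 5,
                             w0 = 1.2, z0 = 0.9)
    s <- runif(2, -2, 2); I <- runif(1, -1, 1)
    g <- central_diff(function(x) pseudopotential(p, x, I), s)
    expect_lt(max(abs(-g / c(p$tau_w, p$tau_z) - drift(p, s, I))), 1e-8)
  }

  # Lyapunov descent under constant drive
  set.seed(71)
  for (k in 1:20) {
    I <- runif(1, -0.5, 0.5)
    tr <- integrate_model(m, runif(2, -1.5, 1.5),
                          stimulus_protocol(I, t_on = 1), t_max = 5)
    V <- vapply(seq_len(nrow(tr)), function(i)
      pseudopotential(m, c(tr$w[i], tr$z[i]), I), 0)
    expect_true(all(diff(V) <= 1e-9))
  }
})

test_that("time constants reshape the flow but do not move equilibria", {
  a <- find_fixed_points(consolidation_model(C_w = 0.3, C_z = 0.3))
  b <- find_fixed_points(consolidation_model(C_w = 0.3, C_z = 0.3, tau_z = 7))
  expect_equal(a$w, b$w)
  expect_equal(a$z, b$z)
  expect_equal(a$classification, b$classification)
})

test_that("parameter files round-trip losslessly", {
  m <- consolidation_model(C_w = 1 / 3, C_z = pi / 7, K_z = 0.1234567890123,
                           tau_z = 7, w0 = sqrt(2), z0 = 1)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_model_params(m, path)
  m2 <- read_model_params(path)
  expect_identical(unclass(m2), unclass(m))
  expect_error(read_model_params({
    p <- withr::local_tempfile(); writeLines("K_w = 1", p); p
  }), "keys")
})
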