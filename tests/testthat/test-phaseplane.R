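test_that("the baseline symmetric model has the expected three equilibria", {
  fp <- find_fixed_points(consolidation_model())
  expect_equal(nrow(fp), 3)
  expect_equal(fp$w, c(-1, 0, 1))
  expect_equal(fp$z, c(-1, 0, 1))
  expect_equal(fp$classification, c("stable", "saddle", "stable"))
  expect_lt(max(abs(vapply(1:3, function(i)
    drift(consolidation_model(), c(fp$w[i], fp$z[i])), c(0, 0)))), 1e-9)
})

test_that("weakening the coupling creates saddles on the anti-diagonal, then four attractors", {
  m4 <- consolidation_model(C_w = 0.4, C_z = 0.4)
  fp4 <- find_fixed_points(m4)
  expect_equal(nrow(fp4), 5)
  # on the w = -z branch the equilibrium condition reduces to w^2 = 1 - 2C
  s <- sqrt(1 - 2 * 0.4)
  new_pts <- fp4[abs(fp4$w) > 1e-6 & abs(abs(fp4$w) - 1) > 1e-6, ]
  expect_equal(sort(new_pts$w), c(-s, s), tolerance = 1e-9)
  expect_equal(new_pts$z, -new_pts$w, tolerance = 1e-9)
  expect_true(all(new_pts$classification == "saddle"))

  fp2 <- find_fixed_points(consolidation_model(C_w = 0.2, C_z = 0.2))
  expect_equal(nrow(fp2), 9)
  expect_equal(sum(fp2$classification == "stable"), 4)
})

test_that("polynomial root finding agrees with a brute-force grid oracle across couplings", {
  vals <- seq(0.13, 1.48, length.out = 10)
  for (cw in vals) for (cz in vals) {
    m <- consolidation_model(C_w = cw, C_z = cz)
    fp <- find_fixed_points(m)
    bf <- brute_fixed_points(m)
    expect_equal(nrow(fp), nrow(bf),
                 label = sprintf("count at C_w=%.2f C_z=%.2f", cw, cz))
    if (nrow(fp) == nrow(bf)) {
      expect_lt(max(abs(cbind(fp$w, fp$z) - bf)), 1e-6)
    }
  }
})

test_that("stability classification matches closed-form eigenvalues", {
  m <- consolidation_model()
  cs <- classify_stability(m, c(1, 1))
  expect_equal(cs$classification, "stable")
  expect_equal(sort(Re(cs$eigenvalues)), c(-4, -2))

  cs0 <- classify_stability(m, c(0, 0))
  expect_equal(cs0$classification, "saddle")
  expect_equal(sort(Re(cs0$eigenvalues)), c(-1, 1))

  # origin eigenvalues for symmetric coupling are {1, 1 - 2C}: both positive
  # below C = 1/2, so the origin becomes a source
  cs4 <- classify_stability(consolidation_model(C_w = 0.4, C_z = 0.4), c(0, 0))
  expect_equal(cs4$classification, "unstable")
  expect_equal(sort(Re(cs4$eigenvalues)), c(1 - 2 * 0.4, 1), tolerance = 1e-12)

  expect_error(classify_stability(m, c(0.3, 0.2)), "not an equilibrium")
})

test_that("basins of the baseline model are split by the anti-diagonal", {
  m <- consolidation_model()
  b <- compute_basins(m, resolution = 60)
  expect_equal(nrow(b$attractors), 2)
  # the only non-convergent cells sit exactly on the separatrix, where the
  # flow runs into the saddle
  spacing <- b$w[2] - b$w[1]
  wz_sum <- outer(b$w, b$z, `+`)
  expect_true(all(abs(wz_sum[b$labels == 0]) < spacing))
  lab_expected <- outer(b$w, b$z, function(w, z) ifelse(w + z > 0, 1, 2))
  upper <- which.min((b$attractors$w - 1)^2)  # index of (1, 1)
  lab_got <- ifelse(b$labels == upper, 1, 2)
  # cells exactly on the diagonal aside, the sign of w + z decides the basin
  off_diag <- abs(wz_sum) > 1e-9 & b$labels > 0
  expect_true(all(lab_got[off_diag] == lab_expected[off_diag]))
})

test_that("basin maps have the point-reflection symmetry of the drive-free flow", {
  m <- consolidation_model(C_w = 0.2, C_z = 0.2)
  b <- compute_basins(m, resolution = 50)
  expect_equal(length(unique(as.vector(b$labels[b$labels > 0]))), 4)
  # reflect (w, z) -> (-w, -z): labels map to the labels of the mirrored attractors
  att <- b$attractors
  mirror <- vapply(seq_len(nrow(att)), function(i)
    which.min((att$w + att$w[i])^2 + (att$z + att$z[i])^2), 0L)
  flipped <- b$labels[rev(seq_along(b$w)), rev(seq_along(b$z))]
  ok <- b$labels > 0 & flipped > 0
  expect_true(all(b$labels[ok] == mirror[flipped[ok]]))
})

test_that("the extracted separatrix follows z = -w and flattens under timescale separation", {
  m <- consolidation_model()
  b <- compute_basins(m, resolution = 100)
  sep <- extract_separatrix(b)
  expect_equal(length(sep$polylines), 1)
  pl <- sep$polylines[[1]]
  spacing <- b$w[2] - b$w[1]
  # perpendicular distance of every vertex from the anti-diagonal
  expect_lt(max(abs(pl$w + pl$z) / sqrt(2)), spacing)

  m7 <- consolidation_model(tau_z = 7)
  s1 <- separatrix_curve(m, w_range = c(1, 1.5), n = 21)
  s7 <- separatrix_curve(m7, w_range = c(1, 1.5), n = 21)
  slope <- function(s) abs(diff(range(s$z)) / diff(range(s$w)))
  expect_lt(slope(s7), slope(s1))

  # monostable map (drive above the fold) has no separatrix
  b1 <- compute_basins(m, input = 0.7, resolution = 30)
  expect_equal(length(extract_separatrix(b1)$polylines), 0)
})

test_that("basin membership follows the relaxation semantics on both sides of the separatrix", {
  m <- consolidation_model()
  expect_true(in_basin(m, c(1, 1), c(1, 1)))
  expect_true(in_basin(m, c(0.1, 0.1), c(1, 1)))
  expect_false(in_basin(m, c(-0.1, 0.05), c(1, 1)))
  expect_error(in_basin(m, c(0, 0), c(0.5, 0.5)), "not a stable fixed point")
})

test_that("the fast separatrix lookup agrees with relaxation labels on a test grid", {
  for (m in list(consolidation_model(), consolidation_model(tau_z = 7))) {
    b <- compute_basins(m, resolution = 50)
    sep <- separatrix_curve(m, n = 81)
    upper <- which.min((b$attractors$w - 1)^2 + (b$attractors$z - 1)^2)
    height <- outer(b$w, b$z, function(w, z)
      z - approx(sep$w, sep$z, xout = w, rule = 2)$y)
    # cells on the separatrix itself (within the bisection tolerance) are
    # knife-edge cases with no well-defined side
    decided <- b$labels > 0 & abs(height) > 1e-6
    expect_true(all((b$labels == upper)[decided] == (height > 0)[decided]))
  }
})

test_that("basin and separatrix exports are well-formed plain text", {
  m <- consolidation_model()
  b <- compute_basins(m, resolution = 25)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_basins(b, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), 25^2)
  expect_named(df, c("w", "z", "label"))
  meta <- jsonlite::read_json(paste0(csv, ".json"))
  expect_equal(meta$resolution, 25)

  sp <- extract_separatrix(b)
  csv2 <- withr::local_tempfile(fileext = ".csv")
  write_separatrix(sp, csv2)
  df2 <- read.csv(csv2)
  expect_named(df2, c("polyline_id", "order", "w", "z"))
  expect_gt(nrow(df2), 0)
})
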