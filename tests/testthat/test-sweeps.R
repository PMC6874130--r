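test_that("single-episode maps respect the DC bound and record areas only on success", {
  m <- consolidation_model()
  sw <- potentiation_map_single(m, amplitudes = c(0, 0.3, 0.5, 1, 2),
                                t_ons = c(0.5, 1, 2, 4, 8))
  # zero-amplitude column and sub-fold amplitudes never potentiate
  expect_true(all(!sw$potentiated[1:3, ]))   # 0, 0.3, 0.5 all below I_c ~ 0.675
  expect_true(any(sw$potentiated[5, ]))
  expect_true(all(is.na(sw$area[!sw$potentiated])))
  pot <- which(sw$potentiated, arr.ind = TRUE)
  for (k in seq_len(nrow(pot)))
    expect_equal(sw$area[pot[k, 1], pot[k, 2]],
                 sw$values1[pot[k, 1]] * sw$values2[pot[k, 2]])
  # repeated runs are identical
  sw2 <- potentiation_map_single(m, amplitudes = c(0, 0.3, 0.5, 1, 2),
                                 t_ons = c(0.5, 1, 2, 4, 8))
  expect_identical(sw$potentiated, sw2$potentiated)
})

test_that("area-parameterized maps snap durations to the grid and flag distorted cells", {
  m <- consolidation_model()
  sw <- potentiation_map_area(m, amplitudes = c(1, 2, 4),
                              areas = c(0.02, 1, 2, 3))
  # area 0.02 at amplitude 4 gives t_on = 0.005 < dt: unevaluable
  expect_true(is.na(sw$potentiated[3, 1]))
  expect_true(is.matrix(sw$flagged))
  # delivered area within 1% unless flagged
  ok <- !is.na(sw$potentiated) & sw$potentiated & !sw$flagged
  idx <- which(ok, arr.ind = TRUE)
  for (k in seq_len(nrow(idx)))
    expect_lt(abs(sw$area[idx[k, 1], idx[k, 2]] - sw$values2[idx[k, 2]]) /
                sw$values2[idx[k, 2]], 0.01)
})

test_that("repeated-episode maps are monotone in amplitude and match the DC limit at t_off = 0", {
  m <- consolidation_model()
  sw <- potentiation_map_repeated(m, amplitudes = c(0.5, 0.6, 0.7, 0.8, 1.2),
                                  t_offs = c(0, 0.5, 1), t_on = 1,
                                  max_episodes = 200)
  # within a column, potentiation is monotone in amplitude with fewer episodes
  for (j in seq_along(sw$values2)) {
    col <- sw$potentiated[, j]
    expect_true(all(diff(col) >= 0))
    eps <- sw$episodes[col, j]
    if (length(eps) > 1) expect_true(all(diff(eps) <= 0))
  }
  # t_off = 0 column is exactly the DC classification at the fold
  ic <- critical_dc_amplitude(m)
  expect_equal(sw$potentiated[, 1], sw$values1 > ic)
})

test_that("the minimal-area search returns a consistent argmin with an episode plateau", {
  m7 <- consolidation_model(tau_z = 7)
  sw <- minimal_area_search(m7, amplitudes = seq(10, 20, by = 1),
                            t_offs = seq(0.05, 0.2, by = 0.01), t_on = 0.01)
  am <- sw$argmin
  expect_equal(am$area, am$episodes * am$amplitude * 0.01)
  expect_true(sw$potentiated[match(am$amplitude, sw$values1),
                             match(am$t_off, sw$values2)])
  expect_lte(am$area, min(sw$area, na.rm = TRUE))
  # the valley around the optimum has a broad, nearly flat bottom: at the
  # argmin amplitude several t_off cells need almost the same total area
  i <- match(am$amplitude, sw$values1)
  near <- sw$area[i, sw$potentiated[i, ]]
  expect_gte(sum(near < am$area * 1.1), 3)

  expect_error(minimal_area_search(m7, amplitudes = c(1, 1.5),
                                   t_offs = c(0.5, 0.6), t_on = 0.01,
                                   max_episodes = 50),
               "no potentiated cell")
})

test_that("separation curves interpolate the outcome boundary and vanish for uniform sweeps", {
  m <- consolidation_model()
  sw <- potentiation_map_single(m, amplitudes = c(1, 1.5, 2, 3),
                                t_ons = seq(0.2, 6, by = 0.2))
  curve <- separation_curve(sw)
  expect_named(curve, c("amplitude", "t_on_critical"))
  expect_true(all(diff(curve$t_on_critical) <= 0))  # shorter episodes suffice at higher drive
  # critical duration sits between a failing and a succeeding grid cell
  for (r in seq_len(nrow(curve))) {
    i <- match(curve$amplitude[r], sw$values1)
    below <- sw$values2 < curve$t_on_critical[r]
    expect_false(any(sw$potentiated[i, below]))
  }

  all_pot <- potentiation_map_repeated(m, amplitudes = c(3, 4),
                                       t_offs = c(0.5, 1), t_on = 1)
  expect_true(all(all_pot$potentiated))
  expect_equal(nrow(separation_curve(all_pot)), 0)
})

test_that("sweep exports round-trip through CSV and JSON", {
  m <- consolidation_model()
  sw <- potentiation_map_repeated(m, amplitudes = c(0.6, 1), t_offs = c(0, 0.5),
                                  t_on = 1, max_episodes = 100)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sweep(sw, f)
  df <- read.csv(f)
  expect_named(df, c("amplitude", "t_off", "potentiated", "episodes", "area"))
  expect_equal(nrow(df), 4)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$t_on, 1)
  expect_equal(unlist(meta$values1), c(0.6, 1))
})
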