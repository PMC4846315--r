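# the heavier simulation fixtures (baseline_fit, set1_trajectory) are
# shared across test files via the helper cache

test_that("constrained minimization preserves areas and lowers energy", {
  ring <- build_ring()
  cav <- default_cavity(ring)
  ts <- population_tensions(ring)
  fit <- baseline_fit()
  expect_lte(fit$energy, total_energy(ring, ts, cav, contact_params()))
  expect_lt(fit$area_residual, 1e-7)
  expect_equal(cell_areas(fit$ring), rep(1, 80), tolerance = 1e-9)
  expect_equal(yolk_area(fit$ring), 600 / 11, tolerance = 1e-7)
  expect_true(all(furrow2d:::cells_simple(fit$ring)))
})

test_that("uniform tensions matched to geometry keep the annulus circular
          with heights at the single-cell preferred value", {
  ring <- build_ring()
  cav <- default_cavity(ring)
  # uniform sigma; alpha + beta matched to the resting aspect so the
  # closed-form preferred height is compatible with the area targets
  ab <- baseline_shape_ratio(ring)
  ts <- population_tensions(ring, sigma = c(ventral = 1, lateral = 1,
                                            dorsal = 1),
                            alpha = ab / 2, beta = ab / 2)
  fit <- minimize_shape(ring, ts, cav)
  r <- sqrt(rowSums(fit$ring$apical^2))
  expect_lt(diff(range(r)), 1e-4)
  h <- lateral_edge_lengths(fit$ring)
  expect_equal(mean(h), preferred_height(ab / 2, ab / 2, 1),
               tolerance = 1e-3)
  expect_lt(diff(range(h)), 1e-3)
})

test_that("pinned vertices stay bit-identical through minimization", {
  ring <- build_ring()
  cav <- default_cavity(ring)
  ts <- population_tensions(ring)
  idx <- c(3L, 17L, 40L)
  coords <- ring$apical[idx, ]
  fit <- minimize_shape(ring, ts, cav, pins = pin_set(idx, coords))
  expect_identical(fit$ring$apical[idx, ], coords)
  expect_error(minimize_shape(ring, ts, cav,
                              pins = pin_set(99L, matrix(0, 1, 2))),
               "invalid pin index")
})

test_that("tension profile follows the t^4 law and the graded taper", {
  ring <- build_ring()
  ts <- population_tensions(ring)
  sch <- ramp_schedule(n_steps = 10)
  v <- which(ring$populations == "ventral")
  expect_equal(apical_tension_profile(0, sch, ring, ts), rep(0, 80))
  # step profile at the end: every ventral cell reaches 3 Gamma_l
  inc <- apical_tension_profile(10, sch, ring, ts)
  expect_equal(inc[v], 3 * ts$Gamma_l[v], tolerance = 1e-12)
  expect_true(all(inc[-v] == 0))
  # temporal factor is (t/n)^4
  inc5 <- apical_tension_profile(5, sch, ring, ts)
  expect_equal(inc5[v], 3 * ts$Gamma_l[v] * 0.5^4, tolerance = 1e-12)
  # graded profile: center reaches the full differential, increments
  # non-increasing from centre outward
  g <- ramp_schedule(n_steps = 10, spatial_profile = "graded",
                     graded_center_gain = 2)
  incg <- apical_tension_profile(10, g, ring, ts)
  ang <- abs(angular_position(ring, v))
  o <- order(ang)
  expect_equal(max(incg[v]), 3 * max(ts$Gamma_l[v]), tolerance = 1e-12)
  expect_true(all(diff(incg[v][o]) < 1e-12))
  expect_equal(min(incg[v]) / max(incg[v]), 1 / 2, tolerance = 0.05)
  expect_error(apical_tension_profile(11, sch, ring, ts), "out of range")
})

test_that("quasi-static set-I ramp: descent, area conservation, symmetry", {
  traj <- set1_trajectory()
  expect_length(traj$configs, 13L)
  expect_lt(max(traj$area_residuals), 1e-5)
  # mirror symmetry of every configuration (midline angle ~ 0)
  for (i in c(1L, 7L, 13L)) {
    expect_lt(abs(midline_angle(traj$configs[[i]], traj$cavity)), 1)
  }
  # the three populations deform as in the wild type: ventral apical
  # constriction, ventral-ward lateral cohort motion, dorsal-dominant
  # dilation
  fin <- traj$configs[[13]]
  ref <- traj$configs[[1]]
  v <- which(fin$populations == "ventral")
  expect_lt(mean(apical_edge_lengths(fin)[v]),
            0.8 * mean(apical_edge_lengths(ref)[v]))
  expect_gt(lateral_displacement(fin, ref)$mean, 0)
  expect_gt(dorsal_dilation(fin, ref), lateral_dilation(fin, ref))
})

test_that("zero-load schedule leaves the relaxed ring unchanged", {
  ring <- build_ring()
  cav <- default_cavity(ring)
  ts <- population_tensions(ring)
  sch <- ramp_schedule(n_steps = 2, final_differential = 0)
  traj <- quasi_static_ramp(ring, ts, cav, sch, seek = seek_params(FALSE))
  d <- max(abs(furrow2d:::ring_state(traj$configs[[3]]) -
                 furrow2d:::ring_state(traj$configs[[1]])))
  expect_lt(d, 1e-3)
})

test_that("minimization is deterministic: identical runs bit-identical", {
  ring <- build_ring()
  cav <- default_cavity(ring)
  ts <- population_tensions(ring)
  f1 <- minimize_shape(ring, ts, cav, control = list(max_outer = 6L))
  f2 <- minimize_shape(ring, ts, cav, control = list(max_outer = 6L))
  expect_identical(f1$ring$apical, f2$ring$apical)
  expect_identical(f1$energy, f2$energy)
})
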