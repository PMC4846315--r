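test_that("seeded generators are reproducible and leave global RNG alone", {
  set.seed(999)
  before <- .Random.seed
  c1 <- gen_recoil_curve(2.7, tau = 0.8, noise_sd = 0.05, seed = 42)
  c2 <- gen_recoil_curve(2.7, tau = 0.8, noise_sd = 0.05, seed = 42)
  expect_identical(c1$speed, c2$speed)
  c3 <- gen_recoil_curve(2.7, tau = 0.8, noise_sd = 0.05, seed = 43)
  expect_false(identical(c1$speed, c3$speed))
  expect_identical(.Random.seed, before)
})

test_that("recoil curves follow the exponential decay model", {
  # noiseless: v(tau) = v0 / e
  cv <- gen_recoil_curve(1.5, tau = 2, noise_sd = 0, n_samples = 41,
                         dt = 0.1)
  i <- which.min(abs(cv$time - 2))
  expect_equal(cv$speed[i], 1.5 / exp(1), tolerance = 1e-12)
  # no-recoil case: mean within 3 sd / sqrt(n) of zero
  cv0 <- gen_recoil_curve(0, tau = 1, noise_sd = 0.05, n_samples = 400,
                          seed = 7)
  expect_lt(abs(mean(cv0$speed)), 3 * 0.05 / sqrt(400))
  expect_error(gen_recoil_curve(-1, 1), "non-negative")
  expect_error(gen_recoil_curve(1, -2), "positive")
  expect_error(gen_recoil_curve(1, 1, noise_sd = -0.1), "non-negative")
})

test_that("log-linear fits recover decay time and initial speed", {
  # ventral-like slow decay vs lateral-like fast decay
  vent <- gen_recoil_curve(1, tau = 4, noise_sd = 0.01, n_samples = 40,
                           dt = 0.1, seed = 2)
  lat <- gen_recoil_curve(2.7, tau = 0.8, noise_sd = 0.01, n_samples = 40,
                          dt = 0.02, seed = 3)
  fv <- fit_recoil(vent)
  fl <- fit_recoil(lat)
  expect_equal(fv$tau, 4, tolerance = 0.2)
  expect_equal(fl$tau, 0.8, tolerance = 0.2)
  expect_gt(fv$tau, fl$tau)        # ventral decays longer than lateral
  expect_equal(fv$v0, 1, tolerance = 0.1)
  expect_equal(fl$v0, 2.7, tolerance = 0.2)
})

test_that("recoil speeds map to relative cortical tensions", {
  sp <- c(ventral = 2, lateral = 5.4, dorsal = 0.15)
  expect_equal(tensions_from_recoil(sp),
               c(ventral = 1, lateral = 2.7, dorsal = 0.075))
  # proportionality: any common factor drops out
  expect_equal(tensions_from_recoil(sp * 13), tensions_from_recoil(sp))
  # no recoil in dorsal cells -> zero dorsal tension
  expect_equal(unname(tensions_from_recoil(
    c(ventral = 1, lateral = 2, dorsal = 0))["dorsal"]), 0)
  # faster lateral recoil -> lateral stiffer than ventral
  expect_gt(tensions_from_recoil(sp)[["lateral"]], 1)
  expect_error(tensions_from_recoil(c(ventral = 0, lateral = 1,
                                      dorsal = 1)), "positive")
  expect_error(tensions_from_recoil(c(lateral = 1, dorsal = 1)),
               "ventral")
})

test_that("small ring fixtures obey the construction contract", {
  r8 <- small_ring_fixture(8)
  expect_equal(r8$n, 8L)
  expect_equal(cell_areas(r8), rep(1, 8), tolerance = 1e-12)
  expect_silent(validate_ring(r8))
  expect_error(small_ring_fixture(3), "between 4 and 16")
  expect_error(small_ring_fixture(18), "between 4 and 16")
  expect_error(small_ring_fixture(7), "even")
})

test_that("noiseless tracks equal the deterministic trajectory", {
  # tiny ring so the ramp is cheap
  ring <- small_ring_fixture(12)
  cav <- default_cavity(ring)
  sch <- ramp_schedule(n_steps = 3)
  ts <- population_tensions(ring, sigma = c(ventral = 1, lateral = 2.7,
                                            dorsal = 0.075))
  traj <- quasi_static_ramp(ring, ts, cav, sch, seek = seek_params(FALSE))
  clean <- trajectory_observables(traj)
  tr0 <- gen_observable_track(2.7, 0.075, noise_sd = 0, seed = 5,
                              clean = clean)
  expect_identical(tr0$observables, clean)
  tr1 <- gen_observable_track(2.7, 0.075, noise_sd = 0.02, seed = 5,
                              clean = clean)
  tr2 <- gen_observable_track(2.7, 0.075, noise_sd = 0.02, seed = 5,
                              clean = clean)
  expect_identical(tr1$observables, tr2$observables)
  expect_false(identical(tr1$observables$furrow_depth,
                         clean$furrow_depth))
  # noise is confined to the observable columns
  expect_identical(tr1$observables$step, clean$step)
  expect_error(gen_observable_track(-1, 0.075), "positive")
})
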