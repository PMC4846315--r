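test_that("parameter sets encode the three tension ratios", {
  expect_equal(parameter_set_sigma("I"),
               c(ventral = 1, lateral = 2.7, dorsal = 0.075))
  expect_equal(parameter_set_sigma("II"),
               c(ventral = 1, lateral = 0.075, dorsal = 2.7))
  expect_equal(parameter_set_sigma("III"),
               c(ventral = 1, lateral = 1, dorsal = 1))
  expect_error(parameter_set_sigma("IV"), "unknown")
  ring <- build_ring()
  ts <- make_parameter_set("I", ring)
  s <- tension_sigma(ts)
  expect_equal(unique(round(s[ring$populations == "lateral_left"], 10)),
               2.7)
  expect_equal(unique(round(s[ring$populations == "dorsal"], 10)), 0.075)
  # alpha and beta shared across populations
  expect_lt(diff(range(tension_alpha(ts))), 1e-12)
})

test_that("cauterization builds the expected pin geometry", {
  ring <- build_ring()
  # +40 deg, width 2 -> 3 consecutive apical vertices on the right side
  p <- cauterize(ring, cauterization_spec(40, 2))
  expect_length(p$indices, 3L)
  expect_true(all(diff(p$indices) == 1L))
  ang <- atan2(ring$apical[p$indices, 2],
               ring$apical[p$indices, 1]) * 180 / pi
  expect_true(all(abs(ang - 40) < 10))
  # bilateral specs give mirror-symmetric pin sets
  pb <- cauterize(ring, cauterization_spec(c(-40, 40), 2))
  angb <- sort(atan2(ring$apical[pb$indices, 2],
                     ring$apical[pb$indices, 1]) * 180 / pi)
  expect_equal(angb, sort(-angb), tolerance = 1e-9)
  # empty spec -> empty pin set
  expect_length(cauterize(ring, cauterization_spec(numeric(0)))$indices,
                0L)
  # overlapping zones are merged with a warning
  expect_warning(cauterize(ring, cauterization_spec(c(40, 43), 2)),
                 "merged")
  expect_error(cauterization_spec(200), "-180")
})

test_that("the six default fixation geometries cover the experiments", {
  specs <- default_cauterization_specs()
  expect_named(specs, c("ventro_lateral_bilateral",
                        "ventro_lateral_unilateral",
                        "mid_lateral_bilateral", "dorso_lateral_bilateral",
                        "dorsal_midline", "double_dorsal"))
  expect_equal(specs$mid_lateral_bilateral$angles, c(-90, 90))
  expect_equal(specs$dorsal_midline$angles, 180)
})

test_that("recoil-based tension inference is exact under proportionality", {
  expect_equal(tensions_from_recoil(c(ventral = 0.4, lateral = 1.08,
                                      dorsal = 0.03)),
               c(ventral = 1, lateral = 2.7, dorsal = 0.075))
})

test_that("tension fitting recovers a grid point from its own output", {
  # tiny synthetic observable surface standing in for ramp output
  grid <- expand.grid(lateral_sigma = c(1, 2.7, 5),
                      dorsal_sigma = c(0.05, 0.075, 0.2))
  grid$furrow_depth <- 0.4 - 0.02 * log(grid$lateral_sigma) +
    0.1 * grid$dorsal_sigma
  grid$dorsal_dilation <- 1.5 - 0.5 * grid$dorsal_sigma +
    0.05 * log(grid$lateral_sigma)
  grid$lateral_displacement <- 2 / grid$lateral_sigma +
    0.3 * grid$dorsal_sigma
  obs <- grid[grid$lateral_sigma == 2.7 & grid$dorsal_sigma == 0.075, ]
  fit <- fit_tensions(obs, grid_obs = grid)
  expect_equal(fit$lateral_sigma, 2.7)
  expect_equal(fit$dorsal_sigma, 0.075)
  # noisy observation still lands within one grid cell (seeded draws)
  hit <- 0L
  for (rep in 1:10) {
    noisy <- obs
    with_seed(100 + rep, {
      for (k in c("furrow_depth", "dorsal_dilation",
                  "lateral_displacement"))
        noisy[[k]] <- noisy[[k]] * (1 + rnorm(1, 0, 0.05))
    })
    f <- fit_tensions(noisy, grid_obs = grid)
    li <- match(f$lateral_sigma, c(1, 2.7, 5))
    di <- match(f$dorsal_sigma, c(0.05, 0.075, 0.2))
    if (abs(li - 2L) <= 1L && abs(di - 2L) <= 1L) hit <- hit + 1L
  }
  expect_gte(hit, 9L)
  # flat surface -> ambiguity error
  flat <- grid
  flat$furrow_depth <- 1
  flat$dorsal_dilation <- 1
  flat$lateral_displacement <- 0
  expect_error(fit_tensions(obs, grid_obs = flat), "ambiguous")
})

test_that("the dorsal-isolation fixation pins the dorsal arc and runs", {
  ring <- small_ring_fixture(16)
  cav <- default_cavity(ring)
  d <- isolation_test(2.7, schedule = ramp_schedule(n_steps = 2),
                      ring = ring, cavity = cav,
                      seek = seek_params(FALSE))
  expect_true(is.finite(d))
  expect_gte(d, 0)
  expect_lte(d, 1)
})

test_that("a battery row classifies depth against the wild type", {
  # structural test on a miniature ring so the full machinery runs end
  # to end quickly; the biological pattern is assessed in the
  # acceptance suite
  ring <- small_ring_fixture(16)
  cav <- default_cavity(ring)
  sch <- ramp_schedule(n_steps = 2)
  out <- cauterization_battery(
    sets = "III",
    specs = list(one = cauterization_spec(180, 1)),
    schedule = sch, ring = ring, cavity = cav,
    seek = seek_params(FALSE))
  expect_equal(nrow(out), 1L)
  expect_true(all(c("set", "spec", "furrow_depth", "wildtype_depth",
                    "permissive", "midline_angle") %in% names(out)))
  expect_false(is.na(out$furrow_depth))
})
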