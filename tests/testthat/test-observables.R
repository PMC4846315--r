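test_that("trivial observable identities hold on the fresh ring", {
  ring <- build_ring()
  cav <- default_cavity(ring)
  # apex on the cavity: depth ~ 0 (midpoint sagitta only)
  expect_lt(furrow_depth(ring, cav), 1e-3)
  expect_equal(dorsal_dilation(ring, ring), 1)
  expect_equal(lateral_dilation(ring, ring), 1)
  expect_equal(lateral_displacement(ring, ring)$mean, 0)
  expect_equal(lateral_displacement(ring, ring)$left, 0)
  expect_lt(abs(midline_angle(ring, cav)), 1e-6)
  # apex dragged to the origin -> depth 1
  deep <- ring
  v1 <- which(ring$populations == "ventral")[5]
  deep$apical[v1, ] <- c(1e-9, 0)
  deep$apical[v1 + 1L, ] <- c(1e-9, 1e-12)
  expect_equal(furrow_depth(deep, cav), 1, tolerance = 1e-6)
})

test_that("furrow depth is invariant under rigid rotation", {
  traj <- set1_trajectory()
  fin <- traj$configs[[length(traj$configs)]]
  cav <- traj$cavity
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- fin
  rot$apical <- fin$apical %*% R
  rot$basal <- fin$basal %*% R
  expect_equal(furrow_depth(rot, cav), furrow_depth(fin, cav),
               tolerance = 1e-12)
})

test_that("mirror-symmetric deformation gives equal per-side displacement", {
  traj <- set1_trajectory()
  fin <- traj$configs[[length(traj$configs)]]
  d <- lateral_displacement(fin, traj$configs[[1]])
  expect_equal(d$left, d$right, tolerance = 1e-4)
})

test_that("kymograph encodes the three deformation modes", {
  traj <- set1_trajectory()
  ky <- simulate_kymograph(traj)
  expect_equal(dim(ky), c(80L, 13L))
  ring <- traj$configs[[1]]
  pops <- as.character(ring$populations)
  spacing <- function(col, idx) {
    a <- sort(ky[idx, col])
    diff(a)
  }
  v <- which(pops == "ventral")
  dI <- which(pops == "dorsal")
  # ventral boundary spacing shrinks (apical constriction), dorsal
  # spacing grows (dilation)
  expect_lt(mean(spacing(13, v)), mean(spacing(1, v)))
  expect_gt(mean(spacing(13, dI)), mean(spacing(1, dI)))
  # lateral boundaries translate ventrally with nearly constant spacing
  lr <- which(pops == "lateral_right")
  expect_lt(abs(mean(spacing(13, lr)) / mean(spacing(1, lr)) - 1), 0.1)
  expect_lt(mean(ky[lr, 13]), mean(ky[lr, 1]))   # toward the midline
  # a zero-length load leaves all rows constant
  sch0 <- ramp_schedule(n_steps = 1, final_differential = 0)
  ring2 <- small_ring_fixture(12)
  ts2 <- population_tensions(ring2, sigma = c(ventral = 1, lateral = 1,
                                              dorsal = 1))
  traj0 <- quasi_static_ramp(ring2, ts2, default_cavity(ring2), sch0,
                             seek = seek_params(FALSE))
  ky0 <- simulate_kymograph(traj0)
  expect_lt(max(abs(ky0[, 2] - ky0[, 1])), 0.1)
})

test_that("observables round-trip bit-identically through snapshots", {
  traj <- set1_trajectory()
  fin <- traj$configs[[length(traj$configs)]]
  cav <- traj$cavity
  path <- tempfile(fileext = ".json")
  write_ring_json(fin, path)
  back <- read_ring_json(path)
  expect_identical(observable_set(back, traj$configs[[1]], cav),
                   observable_set(fin, traj$configs[[1]], cav))
})

test_that("trajectory export writes snapshots plus an observable table", {
  traj <- set1_trajectory()
  dir <- tempfile("traj")
  write_trajectory(traj, dir)
  files <- list.files(dir, pattern = "^step_")
  expect_length(files, length(traj$configs))
  back <- read_trajectory(dir)
  expect_equal(nrow(back$observables), length(traj$configs))
  expect_identical(back$configs[[3]]$apical, traj$configs[[3]]$apical)
})

test_that("cell shape metrics track the post-ramp deformation pattern", {
  traj <- set1_trajectory()
  fin <- traj$configs[[length(traj$configs)]]
  met <- cell_shape_metrics(fin)
  # relative to the relaxed baseline, dorsal apical surfaces dilate
  # while the stiff lateral cohort keeps its apical width and the
  # ventral cells constrict
  ref <- traj$configs[[1]]
  expect_gt(dorsal_dilation(fin, ref), lateral_dilation(fin, ref))
  rel <- apical_edge_lengths(fin) / apical_edge_lengths(ref)
  v <- fin$populations == "ventral"
  expect_lt(mean(rel[v]), 1)
  # metrics remain uniform within the lateral cohort
  lat <- met[met$population == "lateral_left", ]
  expect_lt(stats::sd(lat$width) / mean(lat$width), 0.1)
})
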