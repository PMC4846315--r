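test_that("cavity potential matches the printed pressure law", {
  cav <- vitelline_cavity(r_v = 2, p_0 = 7)
  # zero at the resting radius and inside
  expect_equal(cavity_potential_linedensity(2, cav), 0)
  expect_equal(cavity_potential_linedensity(1.5, cav), 0)
  expect_equal(cavity_pressure(2, cav), 0)
  # p(2 r_v) / p_0 = e - 1
  expect_equal(cavity_pressure(4, cav) / 7, exp(1) - 1, tolerance = 1e-12)
  # dU/dr = p(r) beyond the wall (central differences)
  r <- 1.1 * cav$r_v
  h <- 1e-6
  dU <- (cavity_potential_linedensity(r + h, cav) -
           cavity_potential_linedensity(r - h, cav)) / (2 * h)
  expect_equal(dU, cavity_pressure(r, cav), tolerance = 1e-6)
  expect_error(vitelline_cavity(-1, 10), "positive")
  expect_error(vitelline_cavity(1, 0), "positive")
})

test_that("total energy equals brute-force edge enumeration on fixtures", {
  for (n in c(8L, 12L)) {
    ring <- small_ring_fixture(n)
    ts <- tension_set(1, 1, 1, n = n)
    expect_equal(total_energy(ring, ts),
                 brute_force_energy(ring, ts), tolerance = 1e-10)
    # heterogeneous tensions, perturbed geometry
    ts2 <- with_seed(7, tension_set(runif(n, 0.5, 2), runif(n, 0.5, 2),
                                    runif(n, 0.5, 2), n = n))
    pr <- perturbed_fixture(n)
    expect_equal(total_energy(pr, ts2),
                 brute_force_energy(pr, ts2), tolerance = 1e-10)
  }
})

test_that("energy is rotation-invariant, linear in tensions, zero at zero", {
  ring <- small_ring_fixture(8)
  ts <- tension_set(1.3, 0.7, 1.1, n = 8)
  cav <- default_cavity(ring)
  W <- total_energy(ring, ts, cav)
  th <- 0.73
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- ring
  rot$apical <- ring$apical %*% R
  rot$basal <- ring$basal %*% R
  expect_equal(total_energy(rot, ts, cav), W, tolerance = 1e-10)
  # doubling every tension doubles the tension energy (p_0 = 0 case)
  ts2 <- tension_set(2 * ts$Gamma_a, 2 * ts$Gamma_b, 2 * ts$Gamma_l, n = 8)
  expect_equal(total_energy(ring, ts2), 2 * total_energy(ring, ts),
               tolerance = 1e-12)
  # zero tensions, no cavity -> exactly zero
  ts0 <- tension_set(0, 0, 1e-12, n = 8)
  expect_lt(total_energy(ring, ts0), 1e-10)
})

test_that("analytic gradient matches central differences", {
  ring <- perturbed_fixture(8)
  ts <- with_seed(11, tension_set(runif(8, 0.5, 2), runif(8, 0.5, 2),
                                  runif(8, 0.5, 2), n = 8))
  cav <- vitelline_cavity(max(sqrt(rowSums(ring$apical^2))) * 0.98, 50)
  ct <- contact_params()
  g <- furrow2d:::energy_core(furrow2d:::ring_state(ring), 8, ts, cav, ct,
                              want_grad = TRUE)$grad
  gn <- numerical_gradient(ring, ts, cav, ct)
  expect_lt(max(abs(g - gn)) / max(1, max(abs(gn))), 1e-6)
})

test_that("compiled kernels agree with the plain-R reference", {
  ring <- perturbed_fixture(10, amplitude = 0.1)
  n <- ring$n
  ts <- with_seed(5, tension_set(runif(n, 0.2, 3), runif(n, 0.2, 3),
                                 runif(n, 0.2, 3), n = n))
  cav <- vitelline_cavity(max(sqrt(rowSums(ring$apical^2))) * 0.97, 20)
  ct <- contact_params(range = 0.3, stiffness = 10)
  x <- furrow2d:::ring_state(ring)
  a <- furrow2d:::energy_core(x, n, ts, cav, ct, want_grad = TRUE)
  b <- furrow2d:::energy_core_r(x, n, ts, cav, ct, want_grad = TRUE)
  expect_equal(a$W, b$W, tolerance = 1e-12)
  expect_equal(a$grad, b$grad, tolerance = 1e-12)
  expect_equal(furrow2d:::area_residuals(x, n, 1, 600 / 11),
               furrow2d:::area_residuals_r(x, n, 1, 600 / 11),
               tolerance = 1e-12)
  tw <- with_seed(6, runif(n))
  expect_equal(furrow2d:::area_weighted_grad(x, n, tw, 0.7),
               furrow2d:::area_weighted_grad_r(x, n, tw, 0.7),
               tolerance = 1e-12)
})

test_that("preferred height matches numerical single-cell minimization", {
  # e(w) = (Gamma_a + Gamma_b) w + Gamma_l A / w, h = A / w
  for (case in list(c(1, 1, 1), c(3, 3, 1), c(2, 0.5, 1.7))) {
    al <- case[1]; be <- case[2]; A <- case[3]
    opt <- optimize(function(w) (al + be) * w + A / w, c(1e-3, 50))
    expect_equal(preferred_height(al, be, A), A / opt$minimum,
                 tolerance = 1e-4)
  }
  expect_equal(preferred_height(1, 1, 1), sqrt(2), tolerance = 1e-12)
  expect_equal(preferred_height(3, 3, 1), sqrt(6), tolerance = 1e-12)
  # scaling: 4x the area doubles the height
  expect_equal(preferred_height(2, 1, 4), 2 * preferred_height(2, 1, 1))
  expect_error(preferred_height(-1, 0.5), "positive")
})

test_that("Young modulus: closed form, linearity in sigma, FD response", {
  expect_equal(young_modulus(1, 1, 1, 1), 2 * sqrt(2), tolerance = 1e-12)
  # strictly linear in cortical tension
  expect_equal(young_modulus(2, 3, 2, 1) / young_modulus(2, 3, 1, 1), 2,
               tolerance = 1e-12)
  # closed form vs finite-difference second derivative of e(w) at w*
  draws <- with_seed(13, replicate(20, c(runif(1, 0.5, 4), runif(1, 0.5, 4),
                                         runif(1, 0.3, 3))))
  for (k in seq_len(ncol(draws))) {
    al <- draws[1, k]; be <- draws[2, k]; sg <- draws[3, k]
    Gl <- 2 * sg / (al + be)
    Ga <- al * Gl; Gb <- be * Gl
    e <- function(w) (Ga + Gb) * w + Gl / w
    ws <- sqrt(Gl / (Ga + Gb))
    h <- 1e-4
    d2 <- (e(ws + h) - 2 * e(ws) + e(ws - h)) / h^2
    expect_equal(young_modulus(al, be, sg, 1), ws^2 * d2,
                 tolerance = 1e-3)
  }
  expect_error(young_modulus(1, 1, -1), "positive")
})

test_that("population tensions scale with sigma at fixed alpha, beta", {
  ring <- build_ring()
  ts <- population_tensions(ring, sigma = c(ventral = 1, lateral = 2.7,
                                            dorsal = 0.075))
  expect_equal(unique(round(tension_sigma(ts)[ring$populations ==
                                                "ventral"], 12)), 1)
  expect_equal(unique(round(tension_sigma(ts)[ring$populations ==
                                                "dorsal"], 12)), 0.075)
  # alpha and beta identical across populations
  expect_equal(diff(range(tension_alpha(ts))), 0, tolerance = 1e-12)
  expect_equal(diff(range(tension_beta(ts))), 0, tolerance = 1e-12)
  expect_error(population_tensions(ring, sigma = c(ventral = 1)),
               "lateral")
})
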