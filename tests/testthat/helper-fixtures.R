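# shared fixtures and independent oracles

# brute-force tension energy: enumerate every edge of every cell
# polygon explicitly and sum tension-weighted lengths, counting each
# shared lateral edge once with the mean lateral tension of the two
# cells that share it.  Independent of the package's energy kernel.
brute_force_energy <- function(ring, tensions) {
  n <- ring$n
  seg <- function(p, q) sqrt(sum((p - q)^2))
  W <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    W <- W + tensions$Gamma_a[i] * seg(ring$apical[i, ], ring$apical[j, ])
    W <- W + tensions$Gamma_b[i] * seg(ring$basal[i, ], ring$basal[j, ])
  }
  for (i in seq_len(n)) {        # lateral edge i: apical i -- basal i
    p <- if (i == 1L) n else i - 1L
    w <- (tensions$Gamma_l[i] + tensions$Gamma_l[p]) / 2
    W <- W + w * seg(ring$apical[i, ], ring$basal[i, ])
  }
  W
}

# central finite-difference gradient of the full model energy
numerical_gradient <- function(ring, tensions, cavity = NULL,
                               contact = NULL, h = 1e-6) {
  x <- furrow2d:::ring_state(ring)
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    Wp <- furrow2d:::energy_core(xp, ring$n, tensions, cavity, contact,
                                 want_grad = FALSE)$W
    Wm <- furrow2d:::energy_core(xm, ring$n, tensions, cavity, contact,
                                 want_grad = FALSE)$W
    g[k] <- (Wp - Wm) / (2 * h)
  }
  g
}

# a mildly perturbed small ring (deterministic) for gradient checks
perturbed_fixture <- function(n = 8L, amplitude = 0.05, seed = 42L) {
  ring <- small_ring_fixture(n)
  with_seed(seed, {
    ring$apical <- ring$apical + matrix(rnorm(2 * n, 0, amplitude), n, 2)
    ring$basal <- ring$basal + matrix(rnorm(2 * n, 0, amplitude), n, 2)
  })
  ring
}

# cache for expensive shared computations across test files
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# test-scale schedule used by the heavier simulation tests
test_schedule <- function(n_steps = 12L) ramp_schedule(n_steps = n_steps)

# shared relaxed baseline and set-I trajectory (computed once)
baseline_fit <- function() {
  cached("baseline_fit", {
    ring <- build_ring()
    cav <- default_cavity(ring)
    ts <- population_tensions(ring)
    minimize_shape(ring, ts, cav)
  })
}

set1_trajectory <- function() {
  cached("set1_trajectory", {
    ring <- build_ring()
    cav <- default_cavity(ring)
    ts <- population_tensions(ring)
    quasi_static_ramp(ring, ts, cav, test_schedule(),
                      seek = seek_params(FALSE))
  })
}
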