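#' Evaluate an expression with an isolated RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's global
#' random state afterwards, so no generator call in this package
#' consumes global randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic noisy observable track
#'
#' Emulates an imaging-derived time series of the three deformation
#' observables: runs the deterministic quasi-static ramp at the given
#' ground-truth tensions and adds independent Gaussian noise per
#' observable per step.  The noiseless limit equals the deterministic
#' trajectory; the same seed reproduces the same series.
#'
#' @param lateral_sigma,dorsal_sigma ground-truth cortical tensions
#'   (ventral units).
#' @param noise_sd named numeric vector of additive noise standard
#'   deviations for (a subset of) `furrow_depth`, `dorsal_dilation`,
#'   `lateral_displacement`; a single unnamed number applies to all
#'   three.
#' @param seed integer seed for the noise.
#' @param schedule a [ramp_schedule()].
#' @param ring,cavity geometry (defaults if `NULL`).
#' @param alpha,beta relative tensions (see [population_tensions()]).
#' @param clean optional pre-computed clean observable table (the
#'   output of [trajectory_observables()] for these tensions), reused
#'   across replicates so the ramp is not re-run.
#' @param ... passed to [quasi_static_ramp()].
#' @return A list of class `synthetic_track`: `observables` (noisy
#'   table), `clean`, `truth`, `noise_sd`, `seed`.
#' @export
gen_observable_track <- function(lateral_sigma, dorsal_sigma,
                                 noise_sd = 0, seed = 1L,
                                 schedule = ramp_schedule(),
                                 ring = NULL, cavity = NULL,
                                 alpha = NULL, beta = NULL,
                                 clean = NULL, ...) {
  if (lateral_sigma <= 0 || dorsal_sigma <= 0)
    stop("ground-truth tensions must be positive")
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  keys <- c("furrow_depth", "dorsal_dilation", "lateral_displacement")
  if (is.null(names(noise_sd)) && length(noise_sd) == 1L)
    noise_sd <- stats::setNames(rep(noise_sd, 3L), keys)
  if (is.null(clean)) {
    if (is.null(ring)) ring <- build_ring()
    if (is.null(cavity)) cavity <- default_cavity(ring)
    ts <- population_tensions(
      ring, sigma = c(ventral = 1, lateral = lateral_sigma,
                      dorsal = dorsal_sigma),
      alpha = alpha, beta = beta)
    traj <- quasi_static_ramp(ring, ts, cavity, schedule, ...)
    clean <- trajectory_observables(traj)
  }
  noisy <- clean
  with_seed(seed, {
    for (k in intersect(names(noise_sd), keys)) {
      if (noise_sd[[k]] > 0)
        noisy[[k]] <- noisy[[k]] + stats::rnorm(nrow(noisy), 0, noise_sd[[k]])
    }
  })
  structure(list(observables = noisy, clean = clean,
                 truth = c(lateral_sigma = lateral_sigma,
                           dorsal_sigma = dorsal_sigma),
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_track")
}

#' Synthetic ablation recoil curve
#'
#' Emulates the recoil-speed readout of a laser-ablation experiment as
#' a single-exponential decay `v(t) = sigma_rel * exp(-t / tau)` plus
#' Gaussian noise, with the drag coefficient normalized to 1 so the
#' initial speed equals the relative cortical tension.  `sigma_rel = 0`
#' gives the no-recoil (dorsal) case.
#'
#' @param sigma_rel relative cortical tension (initial speed).
#' @param tau decay time in seconds (ventral-like ~4 s, lateral-like
#'   <1 s); ignored when `sigma_rel = 0`.
#' @param noise_sd additive noise standard deviation.
#' @param n_samples number of samples.
#' @param dt sampling interval in seconds.
#' @param seed integer seed.
#' @return A list of class `recoil_curve`: `time`, `speed`, `v0`,
#'   `tau`, `noise_sd`, `seed`.
#' @export
gen_recoil_curve <- function(sigma_rel, tau = 4, noise_sd = 0.02,
                             n_samples = 50L, dt = 0.1, seed = 1L) {
  if (sigma_rel < 0) stop("sigma_rel must be non-negative")
  if (sigma_rel > 0 && tau <= 0) stop("tau must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  t <- (seq_len(n_samples) - 1L) * dt
  v <- if (sigma_rel == 0) rep(0, n_samples) else sigma_rel * exp(-t / tau)
  if (noise_sd > 0)
    v <- v + with_seed(seed, stats::rnorm(n_samples, 0, noise_sd))
  structure(list(time = t, speed = v, v0 = sigma_rel, tau = tau,
                 noise_sd = noise_sd, seed = seed),
            class = "recoil_curve")
}

#' Fit a recoil curve
#'
#' Log-linear fit of the positive recoil-speed samples: `log v = log v0
#' - t / tau`.  Recovers the initial speed (proportional to cortical
#' tension) and the decay time.
#'
#' @param curve a `recoil_curve` (or any list with `time` and `speed`).
#' @param min_speed samples at or below this speed are dropped before
#'   taking logs.
#' @return A list with `v0` and `tau`.
#' @export
fit_recoil <- function(curve, min_speed = 1e-6) {
  ok <- curve$speed > min_speed
  if (sum(ok) < 3L) stop("too few positive samples to fit a decay")
  fit <- stats::lm(log(curve$speed[ok]) ~ curve$time[ok])
  b <- stats::coef(fit)
  list(v0 = exp(unname(b[1])), tau = -1 / unname(b[2]))
}

#' Miniature ring fixture
#'
#' Small ring (4 to 16 cells, even) with the same area-ratio
#' convention as the default geometry, for brute-force energy and
#' gradient oracles at test scale.
#'
#' @param n_cells even cell count in `[4, 16]`.
#' @param area_ratio cell-to-yolk area ratio.
#' @return An `embryo_ring`.
#' @export
small_ring_fixture <- function(n_cells, area_ratio = 11 / 600) {
  n_cells <- as.integer(n_cells)
  if (n_cells < 4L || n_cells > 16L)
    stop("fixture rings must have between 4 and 16 cells")
  if (n_cells %% 2L != 0L)
    stop("fixture rings must have an even cell count")
  if (n_cells >= 8L) build_ring(n_cells, 2L, 2L, area_ratio)
  else build_ring(n_cells, 1L, 1L, area_ratio)
}
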