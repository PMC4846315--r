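#' Furrow depth
#'
#' Radial ingression of the ventral furrow apex, as a fraction of the
#' vitelline resting radius: `(r_v - min radius over ventral apical
#' edge midpoints) / r_v`, clipped to `[0, 1]`.
#'
#' @param config an `embryo_ring` configuration.
#' @param cavity the `vitelline_cavity` used in the simulation.
#' @return Dimensionless depth in `[0, 1]`.
#' @export
furrow_depth <- function(config, cavity) {
  v <- which(config$populations == "ventral")
  m <- apical_midpoints(config)[v, , drop = FALSE]
  d <- (cavity$r_v - min(sqrt(rowSums(m^2)))) / cavity$r_v
  min(max(d, 0), 1)
}

# mean apical edge length of one population relative to a reference
population_dilation <- function(config, reference, population) {
  i <- which(config$populations %in% population)
  ref <- mean(apical_edge_lengths(reference)[i])
  if (ref <= 0) stop("zero reference apical length")
  mean(apical_edge_lengths(config)[i]) / ref
}

#' Dorsal dilation
#'
#' Mean apical edge length of the dorsal cells divided by the same mean
#' in the reference (undeformed) configuration: circumferential
#' widening of the dorsal tissue.
#'
#' @param config,reference `embryo_ring` configurations with the same
#'   topology.
#' @return Dimensionless ratio (1 means no dilation).
#' @export
dorsal_dilation <- function(config, reference) {
  population_dilation(config, reference, "dorsal")
}

#' Lateral apical dilation
#'
#' As [dorsal_dilation()] but over the two lateral populations; values
#' near 1 indicate the lateral sheets move as a compact cohort without
#' stretching.
#'
#' @inheritParams dorsal_dilation
#' @export
lateral_dilation <- function(config, reference) {
  population_dilation(config, reference, c("lateral_left", "lateral_right"))
}

#' Mean lateral cell displacement
#'
#' Mean tangential (arc-length) displacement of lateral apical edge
#' midpoints relative to the reference, measured along the initial
#' apical radius, signed positive toward the ventral midline.
#'
#' @inheritParams dorsal_dilation
#' @return A list with `left`, `right` (per-side means) and `mean`
#'   (their average), in units of `sqrt(A_c)`.
#' @export
lateral_displacement <- function(config, reference) {
  m0 <- apical_midpoints(reference)
  m1 <- apical_midpoints(config)
  r0 <- sqrt(rowSums(m0^2))
  a0 <- atan2(m0[, 2], m0[, 1])
  a1 <- atan2(m1[, 2], m1[, 1])
  dphi <- atan2(sin(a1 - a0), cos(a1 - a0))
  out <- list()
  for (side in c("left", "right")) {
    i <- which(config$populations ==
                 if (side == "left") "lateral_left" else "lateral_right")
    # toward ventral midline (angle 0): negative dphi on the right
    # (positive angles), positive dphi on the left
    sgn <- if (side == "left") 1 else -1
    out[[side]] <- mean(sgn * r0[i] * dphi[i])
  }
  out$mean <- (out$left + out$right) / 2
  out
}

#' Midline angle
#'
#' Angular position of the furrow apex, in degrees with the convention
#' of [angular_position()]; 0 for a symmetric furrow.  The apex is
#' located as the depth-weighted circular mean of the ventral apical
#' midpoints (weights are squared ingression depths), which degrades
#' gracefully to the symmetric-by-construction value 0 when the furrow
#' is shallow instead of flickering between near-tied minima.
#'
#' @param config an `embryo_ring`.
#' @param cavity optional `vitelline_cavity`; its resting radius is the
#'   depth reference (defaults to the deepest-to-outermost span of the
#'   ventral midpoints themselves).
#' @return Angle in degrees in `(-180, 180]`.
#' @export
midline_angle <- function(config, cavity = NULL) {
  v <- which(config$populations == "ventral")
  m <- apical_midpoints(config)[v, , drop = FALSE]
  r <- sqrt(rowSums(m^2))
  r_ref <- if (is.null(cavity)) max(r) else cavity$r_v
  wts <- pmax(r_ref - r, 0)^2
  if (sum(wts) <= 0) wts <- rep(1, length(r))
  u <- m / r
  ang <- atan2(sum(wts * u[, 2]), sum(wts * u[, 1])) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' All deformation observables of a configuration
#'
#' The three readouts of furrow formation (furrow depth, dorsal
#' dilation, mean lateral displacement) plus the midline angle and the
#' lateral apical dilation (cohort-rigidity check).
#'
#' @param config an `embryo_ring`.
#' @param reference undeformed reference configuration.
#' @param cavity the `vitelline_cavity`.
#' @return A one-row `data.frame` with columns `furrow_depth`,
#'   `dorsal_dilation`, `lateral_displacement`, `midline_angle`,
#'   `lateral_dilation`.
#' @export
observable_set <- function(config, reference, cavity) {
  data.frame(
    furrow_depth = furrow_depth(config, cavity),
    dorsal_dilation = dorsal_dilation(config, reference),
    lateral_displacement = lateral_displacement(config, reference)$mean,
    midline_angle = midline_angle(config, cavity),
    lateral_dilation = lateral_dilation(config, reference)
  )
}

#' Observables along a trajectory
#'
#' @param trajectory a `furrow_trajectory`.
#' @param cavity optional cavity override (defaults to the
#'   trajectory's own).
#' @return A `data.frame` with one row per ramp step (step 0 is the
#'   reference) and the columns of [observable_set()] plus `step` and
#'   `energy`.
#' @export
trajectory_observables <- function(trajectory, cavity = NULL) {
  if (is.null(cavity)) cavity <- trajectory$cavity
  ref <- trajectory$configs[[1]]
  rows <- lapply(seq_along(trajectory$configs), function(i) {
    cbind(step = i - 1L,
          observable_set(trajectory$configs[[i]], ref, cavity),
          energy = trajectory$energies[i])
  })
  do.call(rbind, rows)
}

#' Simulated kymograph
#'
#' Angular positions of every apical cell boundary (vertex) at every
#' ramp step: rows are boundaries (cyclically ordered at step 0),
#' columns are steps.  Angles are in degrees, unwrapped along time so
#' trajectories crossing the dorsal midline stay continuous.
#'
#' @param trajectory a `furrow_trajectory`.
#' @return A numeric matrix of dimension `n x (n_steps + 1)`, class
#'   `kymograph`.
#' @export
simulate_kymograph <- function(trajectory) {
  if (!length(trajectory$configs)) stop("empty trajectory")
  ang <- sapply(trajectory$configs, function(cf) {
    atan2(cf$apical[, 2], cf$apical[, 1]) * 180 / pi
  })
  ang <- matrix(ang, nrow = trajectory$configs[[1]]$n)
  if (ncol(ang) > 1) {
    for (j in 2:ncol(ang)) {
      d <- ang[, j] - ang[, j - 1]
      d <- (d + 180) %% 360 - 180
      ang[, j] <- ang[, j - 1] + d
    }
  }
  structure(ang, class = c("kymograph", "matrix"))
}

#' Per-cell shape metrics
#'
#' Width (mean of apical and basal edge lengths), height (mean of the
#' two lateral edge lengths) and aspect ratio (height/width) for every
#' cell.
#'
#' @param config an `embryo_ring`.
#' @return A `data.frame` with columns `cell`, `population`, `width`,
#'   `height`, `aspect`.
#' @export
cell_shape_metrics <- function(config) {
  n <- config$n
  nxt <- c(seq_len(n)[-1], 1L)
  la <- apical_edge_lengths(config)
  lb <- basal_edge_lengths(config)
  ll <- lateral_edge_lengths(config)
  width <- (la + lb) / 2
  height <- (ll + ll[nxt]) / 2
  data.frame(cell = seq_len(n), population = config$populations,
             width = width, height = height, aspect = height / width)
}
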