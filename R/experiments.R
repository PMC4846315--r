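#' Cortical-tension parameter sets
#'
#' The three relative cortical-tension assignments
#' (ventral : lateral : dorsal) used in the in-silico studies:
#' set I is the best-fit ratio `1 : 2.7 : 0.075`; set II swaps lateral
#' and dorsal (`1 : 0.075 : 2.7`); set III makes all three populations
#' identical (`1 : 1 : 1`), leaving apical constriction as the only
#' difference.
#'
#' @param name one of `"I"`, `"II"`, `"III"`.
#' @return Named numeric vector with entries `ventral`, `lateral`,
#'   `dorsal`.
#' @export
parameter_set_sigma <- function(name) {
  switch(as.character(name),
         "I"   = c(ventral = 1, lateral = 2.7, dorsal = 0.075),
         "II"  = c(ventral = 1, lateral = 0.075, dorsal = 2.7),
         "III" = c(ventral = 1, lateral = 1, dorsal = 1),
         stop("unknown parameter set: ", name))
}

#' @rdname parameter_set_sigma
#' @param ring an `embryo_ring`.
#' @param alpha,beta relative apical/basal tensions passed to
#'   [population_tensions()].
#' @return `make_parameter_set` returns the per-cell `tension_set`.
#' @export
make_parameter_set <- function(name, ring, alpha = NULL, beta = NULL) {
  population_tensions(ring, sigma = parameter_set_sigma(name),
                      alpha = alpha, beta = beta)
}

# shared runner: ramp at given population sigmas, return final-state
# observables (one row) plus the trajectory if requested
run_condition <- function(ring, sigma, cavity, schedule, pins = NULL,
                          alpha = NULL, beta = NULL, tol = shape_tol(),
                          contact = contact_params(), seek = seek_params(),
                          control = list(), keep_trajectory = FALSE) {
  ts <- population_tensions(ring, sigma = sigma, alpha = alpha, beta = beta)
  traj <- quasi_static_ramp(ring, ts, cavity, schedule, pins = pins,
                            tol = tol, contact = contact, seek = seek,
                            control = control)
  fin <- traj$configs[[length(traj$configs)]]
  obs <- observable_set(fin, traj$configs[[1]], cavity)
  if (keep_trajectory) list(observables = obs, trajectory = traj)
  else list(observables = obs)
}

#' Phase diagram over lateral and dorsal cortical tensions
#'
#' Runs a full quasi-static ramp at every point of the
#' `(lateral sigma, dorsal sigma)` grid (ventral fixed at 1) and records
#' the final-state observables.  Grid points satisfying all three
#' best-fit criteria are marked: (a) furrow depth at least `depth_frac`
#' of the grid maximum (full internalization), (b) lateral apical
#' dilation within `cohort_tol` of 1 (the lateral sheets move as rigid
#' cohorts), (c) dorsal dilation exceeding lateral dilation
#' (dorsal-dominant stretching).
#'
#' @param lat_grid,dor_grid positive tension grids (ventral units).
#' @param schedule a [ramp_schedule()].
#' @param ring an `embryo_ring` (default ring if `NULL`).
#' @param cavity a `vitelline_cavity` (default cavity if `NULL`).
#' @param alpha,beta relative tensions (see [population_tensions()]).
#' @param depth_frac,cohort_tol best-fit thresholds (see above).
#' @param verbose print progress.
#' @param ... passed to [quasi_static_ramp()] (`tol`, `contact`,
#'   `seek`, `control`).
#' @return A list of class `phase_diagram` with `grid` (a `data.frame`
#'   of grid points, observables, `converged` flag and `best_fit`
#'   mask) and the run settings.
#' @export
phase_diagram <- function(lat_grid, dor_grid, schedule = ramp_schedule(),
                          ring = NULL, cavity = NULL,
                          alpha = NULL, beta = NULL,
                          depth_frac = 0.9, cohort_tol = 0.05,
                          verbose = FALSE, ...) {
  if (any(lat_grid <= 0) || any(dor_grid <= 0))
    stop("tension grids must be positive")
  if (is.null(ring)) ring <- build_ring()
  if (is.null(cavity)) cavity <- default_cavity(ring)
  pts <- expand.grid(lateral_sigma = lat_grid, dorsal_sigma = dor_grid,
                     KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    sg <- c(ventral = 1, lateral = pts$lateral_sigma[i],
            dorsal = pts$dorsal_sigma[i])
    res <- tryCatch(
      run_condition(ring, sg, cavity, schedule, alpha = alpha, beta = beta,
                    ...),
      error = function(e) NULL)
    if (is.null(res)) {
      rows[[i]] <- data.frame(furrow_depth = NA_real_,
                              dorsal_dilation = NA_real_,
                              lateral_displacement = NA_real_,
                              midline_angle = NA_real_,
                              lateral_dilation = NA_real_,
                              converged = FALSE)
    } else {
      rows[[i]] <- cbind(res$observables, converged = TRUE)
    }
    if (verbose)
      message(sprintf("phase point (%g, %g): depth %.3f",
                      pts$lateral_sigma[i], pts$dorsal_sigma[i],
                      rows[[i]]$furrow_depth))
  }
  grid <- cbind(pts, do.call(rbind, rows))
  grid$best_fit <- with(grid, converged &
    furrow_depth >= depth_frac * max(furrow_depth, na.rm = TRUE) &
    abs(lateral_dilation - 1) <= cohort_tol &
    dorsal_dilation > lateral_dilation)
  grid$best_fit[is.na(grid$best_fit)] <- FALSE
  structure(list(grid = grid, depth_frac = depth_frac,
                 cohort_tol = cohort_tol, schedule = schedule),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("<phase_diagram> ", nrow(x$grid), " grid points, ",
      sum(x$grid$best_fit), " in the best-fit region\n", sep = "")
  print(x$grid, digits = 4)
  invisible(x)
}

#' Centroid of the best-fit region along the lateral-tension axis
#'
#' Geometric mean of the lateral cortical tensions of the grid points
#' in the best-fit mask; the model's prediction of the
#' lateral-to-ventral cortical tension ratio.
#'
#' @param pd a `phase_diagram`.
#' @return Scalar tension (ventral units), or `NA` if the mask is empty.
#' @export
best_fit_lateral_centroid <- function(pd) {
  s <- pd$grid$lateral_sigma[pd$grid$best_fit]
  if (!length(s)) return(NA_real_)
  exp(mean(log(s)))
}

#' Cauterization specification
#'
#' Fixation sites given as angular positions (degrees, convention of
#' [angular_position()]): at each angle, the apical vertices of the
#' `width` nearest cells are pinned at their current (cavity-contact)
#' coordinates.
#'
#' @param angles numeric vector of fixation angles in `(-180, 180]`.
#' @param width per-fixation width in cells (default 2).
#' @export
cauterization_spec <- function(angles, width = 2L) {
  if (length(angles) && (any(angles <= -180) || any(angles > 180)))
    stop("fixation angles must lie in (-180, 180]")
  if (width < 1L) stop("width must be at least 1 cell")
  list(angles = as.numeric(angles), width = as.integer(width))
}

#' The six modelled cauterization experiments
#'
#' Fixation geometries mirroring the imaging experiments: bilateral
#' ventro-lateral (+/-40 deg), unilateral ventro-lateral (+40 deg),
#' bilateral mid-lateral (+/-90 deg), bilateral dorso-lateral
#' (+/-135 deg), a single dorsal-midline fixation (180 deg) and a
#' double dorsal fixation (+/-160 deg).
#'
#' @param width per-fixation width in cells.
#' @return Named list of [cauterization_spec()]s.
#' @export
default_cauterization_specs <- function(width = 2L) {
  list(
    ventro_lateral_bilateral = cauterization_spec(c(-40, 40), width),
    ventro_lateral_unilateral = cauterization_spec(40, width),
    mid_lateral_bilateral = cauterization_spec(c(-90, 90), width),
    dorso_lateral_bilateral = cauterization_spec(c(-135, 135), width),
    dorsal_midline = cauterization_spec(180, width),
    double_dorsal = cauterization_spec(c(-160, 160), width)
  )
}

#' Build the pin set of a cauterization
#'
#' @param ring an `embryo_ring` in its pre-fixation (cavity-contact)
#'   configuration.
#' @param spec a [cauterization_spec()].
#' @return A [pin_set()] pinning the apical vertices of the selected
#'   cells at their current coordinates.  Overlapping fixation zones
#'   are merged with a warning.
#' @export
cauterize <- function(ring, spec) {
  if (!length(spec$angles)) return(pin_set())
  n <- ring$n
  cell_ang <- angular_position(ring, seq_len(n))
  vset <- list()
  for (a in spec$angles) {
    d <- abs(atan2(sin((cell_ang - a) * pi / 180),
                   cos((cell_ang - a) * pi / 180)))
    cells <- order(d)[seq_len(spec$width)]
    vset[[length(vset) + 1L]] <-
      sort(unique(c(cells, ifelse(cells == n, 1L, cells + 1L))))
  }
  all_v <- unlist(vset)
  if (anyDuplicated(all_v))
    warning("overlapping fixation zones merged")
  idx <- sort(unique(all_v))
  pin_set(idx, ring$apical[idx, , drop = FALSE])
}

#' Cauterization battery
#'
#' Runs the full quasi-static ramp for each tension parameter set and
#' each fixation geometry, plus the unpinned wild-type run per set, and
#' classifies each fixation as permissive (final furrow depth at least
#' `permissive_frac` of that set's wild-type depth) or non-permissive.
#'
#' @param sets character vector of parameter-set names (see
#'   [parameter_set_sigma()]).
#' @param specs named list of [cauterization_spec()]s.
#' @param schedule a [ramp_schedule()].
#' @param ring,cavity geometry (defaults if `NULL`).
#' @param alpha,beta relative tensions.
#' @param permissive_frac permissive threshold as a fraction of the
#'   same set's unpinned depth.
#' @param verbose print progress.
#' @param ... passed to [quasi_static_ramp()].
#' @return A `data.frame` with one row per (set, spec): furrow depth,
#'   wild-type depth, permissive flag, midline angle.  Failed runs
#'   propagate as `NA` rows without aborting the battery.
#' @export
cauterization_battery <- function(sets = c("I", "II", "III"),
                                  specs = default_cauterization_specs(),
                                  schedule = ramp_schedule(),
                                  ring = NULL, cavity = NULL,
                                  alpha = NULL, beta = NULL,
                                  permissive_frac = 0.5,
                                  verbose = FALSE, ...) {
  if (is.null(ring)) ring <- build_ring()
  if (is.null(cavity)) cavity <- default_cavity(ring)
  out <- list()
  for (s in sets) {
    sg <- parameter_set_sigma(s)
    wt <- tryCatch(
      run_condition(ring, sg, cavity, schedule, alpha = alpha, beta = beta,
                    ...),
      error = function(e) NULL)
    wt_depth <- if (is.null(wt)) NA_real_ else wt$observables$furrow_depth
    if (verbose) message(sprintf("set %s wild-type depth: %.3f", s, wt_depth))
    for (nm in names(specs)) {
      pins <- cauterize(ring, specs[[nm]])
      res <- tryCatch(
        run_condition(ring, sg, cavity, schedule, pins = pins,
                      alpha = alpha, beta = beta, ...),
        error = function(e) NULL)
      row <- data.frame(
        set = s, spec = nm,
        furrow_depth = if (is.null(res)) NA_real_
                       else res$observables$furrow_depth,
        wildtype_depth = wt_depth,
        midline_angle = if (is.null(res)) NA_real_
                        else res$observables$midline_angle,
        stringsAsFactors = FALSE)
      row$permissive <- !is.na(row$furrow_depth) & !is.na(wt_depth) &
        row$furrow_depth >= permissive_frac * wt_depth
      if (verbose)
        message(sprintf("  %s: depth %.3f (%s)", nm, row$furrow_depth,
                        if (isTRUE(row$permissive)) "permissive"
                        else "non-permissive"))
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Dorsal-isolation test
#'
#' The theoretical cauterization that isolates the dorsal tissue plus
#' the dorsal half of each lateral block from the constricting ventral
#' cells: all apical vertices of those cells are pinned, the ramp is
#' run, and the final furrow depth is returned.  With a stiff enough
#' lateral population the remaining free lateral cells cannot deform
#' and the furrow fails to internalize.
#'
#' @param lateral_sigma lateral cortical tension (ventral units).
#' @param schedule a [ramp_schedule()].
#' @param ring,cavity geometry (defaults if `NULL`).
#' @param dorsal_sigma dorsal cortical tension.
#' @param alpha,beta relative tensions.
#' @param ... passed to [quasi_static_ramp()].
#' @return Final furrow depth (fraction of r_v).
#' @export
isolation_test <- function(lateral_sigma, schedule = ramp_schedule(),
                           ring = NULL, cavity = NULL,
                           dorsal_sigma = 0.075,
                           alpha = NULL, beta = NULL, ...) {
  if (lateral_sigma <= 0) stop("lateral_sigma must be positive")
  if (is.null(ring)) ring <- build_ring()
  if (is.null(cavity)) cavity <- default_cavity(ring)
  pm <- population_map(ring)
  ang <- angular_position(ring, seq_len(ring$n))
  iso_cells <- pm$dorsal
  for (side in c("lateral_left", "lateral_right")) {
    i <- pm[[side]]
    keep <- i[order(-abs(ang[i]))]          # most dorsal first
    iso_cells <- c(iso_cells, keep[seq_len(ceiling(length(i) / 2))])
  }
  idx <- sort(unique(c(iso_cells,
                       ifelse(iso_cells == ring$n, 1L, iso_cells + 1L))))
  pins <- pin_set(idx, ring$apical[idx, , drop = FALSE])
  sg <- c(ventral = 1, lateral = lateral_sigma, dorsal = dorsal_sigma)
  res <- run_condition(ring, sg, cavity, schedule, pins = pins,
                       alpha = alpha, beta = beta, ...)
  res$observables$furrow_depth
}

#' Fit cortical tensions to observed deformation observables
#'
#' Grid search: the model observables are computed (or supplied
#' pre-computed) on a `(lateral, dorsal)` tension grid, each observable
#' is standardized by its spread across the grid, and the grid point
#' minimizing the sum of squared standardized mismatches to the
#' observation is returned.  Ties break toward smaller lateral then
#' smaller dorsal tension.
#'
#' @param observed named list / one-row data.frame with
#'   `furrow_depth`, `dorsal_dilation`, `lateral_displacement`.
#' @param lat_grid,dor_grid tension grids (ignored when `grid_obs`
#'   supplied).
#' @param schedule a [ramp_schedule()].
#' @param ring,cavity geometry (defaults if `NULL`).
#' @param grid_obs optional pre-computed grid observables (the `grid`
#'   data.frame of a [phase_diagram()]), reused across repeated fits.
#' @param alpha,beta relative tensions.
#' @param ... passed to [phase_diagram()] when the grid is computed.
#' @return List with `lateral_sigma`, `dorsal_sigma`, and `misfit` (the
#'   grid data.frame with a `misfit` column).
#' @export
fit_tensions <- function(observed, lat_grid = NULL, dor_grid = NULL,
                         schedule = ramp_schedule(), ring = NULL,
                         cavity = NULL, grid_obs = NULL,
                         alpha = NULL, beta = NULL, ...) {
  if (is.null(grid_obs)) {
    pd <- phase_diagram(lat_grid, dor_grid, schedule, ring = ring,
                        cavity = cavity, alpha = alpha, beta = beta, ...)
    grid_obs <- pd$grid
  }
  keys <- c("furrow_depth", "dorsal_dilation", "lateral_displacement")
  z <- 0
  any_spread <- FALSE
  for (k in keys) {
    s <- stats::sd(grid_obs[[k]], na.rm = TRUE)
    if (is.na(s) || s == 0) next
    any_spread <- TRUE
    z <- z + ((grid_obs[[k]] - observed[[k]]) / s)^2
  }
  if (!any_spread)
    stop("ambiguous fit: observables have no spread across the grid")
  grid_obs$misfit <- z
  o <- order(z, grid_obs$lateral_sigma, grid_obs$dorsal_sigma)
  best <- grid_obs[o[1], ]
  list(lateral_sigma = best$lateral_sigma,
       dorsal_sigma = best$dorsal_sigma,
       misfit = grid_obs)
}

#' Cortical tensions from ablation recoil speeds
#'
#' With uniform effective drag, the initial recoil speed after laser
#' ablation is proportional to the local cortical tension, so relative
#' tensions are recoil speeds divided by the ventral speed.
#'
#' @param speeds named numeric vector with entries `ventral`,
#'   `lateral`, `dorsal` (initial recoil speeds, any common unit).
#' @return Named vector of relative cortical tensions (ventral = 1).
#' @export
tensions_from_recoil <- function(speeds) {
  need <- c("ventral", "lateral", "dorsal")
  if (!all(need %in% names(speeds)))
    stop("speeds must have entries ventral, lateral, dorsal")
  if (any(speeds < 0)) stop("recoil speeds must be non-negative")
  if (speeds[["ventral"]] <= 0)
    stop("ventral recoil speed must be positive (it defines the unit)")
  out <- speeds[need] / speeds[["ventral"]]
  names(out) <- need
  out
}
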