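#' Default run configuration
#'
#' All model parameters of a simulation run.  The defaults reproduce
#' the wild-type best-fit condition: 80 cells with 10 ventral
#' constricting cells, cell-to-yolk area ratio 11/600, a rigid
#' vitelline shell (`p_0 = 1000`), cortical tensions 1 : 2.7 : 0.075
#' (ventral : lateral : dorsal), and a 50-step `t^4` ramp to a final
#' ventral differential tension of `3 Gamma_l`.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    n_cells = 80L,
    n_ventral = 10L,
    n_dorsal = 20L,
    area_ratio = 11 / 600,
    p_0 = 1000,
    r_v = NULL,                # NULL: apical radius of the fresh ring
    alpha = NULL,              # NULL: resting-shape default, see vignette
    beta = NULL,
    sigma_ventral = 1,
    sigma_lateral = 2.7,
    sigma_dorsal = 0.075,
    n_steps = 50L,
    time_exponent = 4,
    final_differential = 3,
    spatial_profile = "step",
    graded_center_gain = 2,
    contact_range = 0.12,
    contact_stiffness = 200,
    tol_area = 1e-7,
    tol_grad = 2e-3,
    cauterization_angles = numeric(0),
    cauterization_width = 2L,
    seed = 1L,
    output_dir = "furrow2d-output"
  ), class = "run_config")
}

#' Load / save a run configuration
#'
#' YAML round trip of a [default_config()]-shaped configuration.
#' Unknown keys are an error (listing them); missing keys fall back to
#' the defaults with a message.  Basic validity (positive stiffness,
#' counts, tensions) is checked on load.
#'
#' @param path file path.
#' @return `load_config` returns a `run_config`; `save_config` writes
#'   the file and returns `path` invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  def <- default_config()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(names(def), names(raw))
  missing <- missing[!vapply(def[missing], is.null, logical(1))]
  if (length(missing))
    message("using defaults for: ", paste(missing, collapse = ", "))
  cfg <- utils::modifyList(def, raw, keep.null = TRUE)
  # integer-valued keys arrive as numerics from YAML, empty sequences
  # as lists
  for (k in c("n_cells", "n_ventral", "n_dorsal", "n_steps",
              "cauterization_width", "seed"))
    cfg[[k]] <- as.integer(cfg[[k]])
  cfg$cauterization_angles <- as.numeric(unlist(cfg$cauterization_angles))
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
save_config <- function(config, path) {
  validate_config(config)
  out <- config[!vapply(config, is.null, logical(1))]
  # emit doubles verbatim at full precision so the round trip is exact
  num_handler <- function(x) {
    s <- vapply(x, function(v) format(v, digits = 17), character(1))
    if (length(s) == 1L) structure(s, class = "verbatim")
    else lapply(s, function(v) structure(v, class = "verbatim"))
  }
  yaml::write_yaml(out, path, handlers = list(numeric = num_handler))
  invisible(path)
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_cells >= 4, cfg$n_ventral >= 1, cfg$n_dorsal >= 1)
  if (cfg$area_ratio <= 0) stop("area_ratio must be positive")
  if (cfg$p_0 <= 0) stop("p_0 must be positive")
  if (!is.null(cfg$r_v) && cfg$r_v <= 0) stop("r_v must be positive")
  if (cfg$n_steps < 1) stop("n_steps must be at least 1")
  if (cfg$final_differential < 0)
    stop("final_differential must be non-negative")
  if (any(c(cfg$sigma_ventral, cfg$sigma_lateral, cfg$sigma_dorsal) <= 0))
    stop("cortical tensions must be positive")
  if (!cfg$spatial_profile %in% c("step", "graded"))
    stop("spatial_profile must be 'step' or 'graded'")
  invisible(cfg)
}

#' Assemble model objects from a configuration
#'
#' @param config a `run_config`.
#' @return A list with `ring`, `tensions`, `cavity`, `schedule`,
#'   `pins`, `contact`, `tol`.
#' @export
setup_from_config <- function(config) {
  validate_config(config)
  ring <- build_ring(config$n_cells, config$n_ventral, config$n_dorsal,
                     config$area_ratio)
  cavity <- if (is.null(config$r_v)) default_cavity(ring, config$p_0)
            else vitelline_cavity(config$r_v, config$p_0)
  tensions <- population_tensions(
    ring, sigma = c(ventral = config$sigma_ventral,
                    lateral = config$sigma_lateral,
                    dorsal = config$sigma_dorsal),
    alpha = config$alpha, beta = config$beta)
  schedule <- ramp_schedule(config$n_steps, config$time_exponent,
                            config$final_differential,
                            config$spatial_profile,
                            config$graded_center_gain)
  pins <- if (length(config$cauterization_angles))
    cauterize(ring, cauterization_spec(config$cauterization_angles,
                                       config$cauterization_width))
  else pin_set()
  list(ring = ring, tensions = tensions, cavity = cavity,
       schedule = schedule, pins = pins,
       contact = contact_params(config$contact_range,
                                config$contact_stiffness),
       tol = shape_tol(config$tol_area, config$tol_grad))
}

#' Ring snapshot serialization
#'
#' Writes / reads an `embryo_ring` as JSON
#' (`{apical, basal, populations, targets}`) at full floating-point
#' precision, so a reload reproduces the vertex arrays bit for bit.
#'
#' @param ring an `embryo_ring`.
#' @param path file path.
#' @export
write_ring_json <- function(ring, path) {
  obj <- list(apical = unclass(ring$apical),
              basal = unclass(ring$basal),
              populations = as.character(ring$populations),
              targets = list(A_c = ring$target_cell_area,
                             A_y = ring$target_yolk_area))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ring_json
#' @return `read_ring_json` returns the reconstructed `embryo_ring`
#'   (validated); a corrupted file is a parse error, never a partial
#'   object.
#' @export
read_ring_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("apical", "basal", "populations", "targets")
  if (!all(need %in% names(obj)))
    stop("not a ring snapshot: missing ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  ring <- structure(list(
    apical = matrix(as.numeric(obj$apical), ncol = 2),
    basal = matrix(as.numeric(obj$basal), ncol = 2),
    n = nrow(obj$apical),
    populations = factor(obj$populations,
                         levels = c("ventral", "lateral_right", "dorsal",
                                    "lateral_left")),
    target_cell_area = obj$targets$A_c,
    target_yolk_area = obj$targets$A_y
  ), class = "embryo_ring")
  validate_ring(ring)
  ring
}

#' Trajectory export / import
#'
#' Writes one JSON snapshot per ramp step (`step_000.json`, ...) plus a
#' CSV of per-step observables and energies; `read_trajectory` restores
#' the configurations bit-identically.
#'
#' @param trajectory a `furrow_trajectory`.
#' @param dir output directory (created if needed).
#' @param snapshot_every write every k-th configuration (the first and
#'   last are always written).
#' @export
write_trajectory <- function(trajectory, dir, snapshot_every = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(trajectory$configs)
  keep <- unique(c(seq(1L, n, by = snapshot_every), n))
  for (i in keep)
    write_ring_json(trajectory$configs[[i]],
                    file.path(dir, sprintf("step_%03d.json", i - 1L)))
  obs <- trajectory_observables(trajectory)
  obs$area_residual <- trajectory$area_residuals
  utils::write.csv(obs, file.path(dir, "observables.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_trajectory
#' @return `read_trajectory` returns a list with `configs` (in step
#'   order) and `observables`.
#' @export
read_trajectory <- function(dir) {
  files <- sort(list.files(dir, pattern = "^step_[0-9]+\\.json$",
                           full.names = TRUE))
  configs <- lapply(files, read_ring_json)
  obs_file <- file.path(dir, "observables.csv")
  observables <- if (file.exists(obs_file))
    utils::read.csv(obs_file) else NULL
  list(configs = configs, observables = observables)
}
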