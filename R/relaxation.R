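#' Pinned-vertex set (in-silico cauterization)
#'
#' Apical vertices held immobile at fixed coordinates during energy
#' minimization, the model analogue of fusing tissue to the vitelline
#' membrane.
#'
#' @param indices apical vertex indices.
#' @param coords matrix of fixed coordinates, one row per index.
#' @return An object of class `pin_set`.
#' @export
pin_set <- function(indices = integer(0), coords = NULL) {
  indices <- as.integer(indices)
  if (length(indices) == 0L)
    return(structure(list(indices = integer(0),
                          coords = matrix(numeric(0), 0, 2)),
                     class = "pin_set"))
  if (is.null(coords) || nrow(coords) != length(indices))
    stop("coords must supply one row per pinned vertex")
  o <- order(indices)
  structure(list(indices = indices[o],
                 coords = as.matrix(coords)[o, , drop = FALSE]),
            class = "pin_set")
}

#' @export
print.pin_set <- function(x, ...) {
  cat("<pin_set> ", length(x$indices), " pinned apical vertices\n", sep = "")
  invisible(x)
}

# constraint residuals c = (cell areas - A_c, yolk area - A_y);
# compiled kernel with area_residuals_r as the plain-R reference
area_residuals <- function(x, n, a_c, a_y) {
  .area_residuals_cpp(x, as.integer(n), a_c, a_y)
}

area_residuals_r <- function(x, n, a_c, a_y) {
  idx <- seq_len(n); nxt <- c(idx[-1], 1L)
  A <- cbind(x[idx], x[n + idx])
  B <- cbind(x[2 * n + idx], x[3 * n + idx])
  An <- A[nxt, , drop = FALSE]; Bn <- B[nxt, , drop = FALSE]
  cr <- function(u, v) u[, 1] * v[, 2] - u[, 2] * v[, 1]
  cells <- (cr(A, An) + cr(An, Bn) + cr(Bn, B) + cr(B, A)) / 2
  yolk <- sum(cr(B, Bn)) / 2
  c(cells - a_c, yolk - a_y)
}

# constraint Jacobian: rows = N cell areas then yolk area, columns =
# flat coordinates (apical x, apical y, basal x, basal y)
constraint_jacobian <- function(x, n) {
  idx <- seq_len(n); nxt <- c(idx[-1], 1L); prv <- c(n, idx[-n])
  A <- cbind(x[idx], x[n + idx])
  B <- cbind(x[2 * n + idx], x[3 * n + idx])
  An <- A[nxt, , drop = FALSE]; Bn <- B[nxt, , drop = FALSE]
  Bp <- B[prv, , drop = FALSE]; Ap <- A[prv, , drop = FALSE]
  J <- matrix(0, n + 1L, 4L * n)
  # cell i polygon (a_i, a_{i+1}, b_{i+1}, b_i); vertex gradient is
  # 0.5 * (next_y - prev_y, prev_x - next_x)
  put <- function(rows, cols, vals) J[cbind(rows, cols)] <<- J[cbind(rows, cols)] + vals
  put(idx, idx,           0.5 * (An[, 2] - B[, 2]))   # d/d a_i.x
  put(idx, n + idx,       0.5 * (B[, 1] - An[, 1]))   # d/d a_i.y
  put(idx, nxt,           0.5 * (Bn[, 2] - A[, 2]))   # d/d a_{i+1}.x
  put(idx, n + nxt,       0.5 * (A[, 1] - Bn[, 1]))   # d/d a_{i+1}.y
  put(idx, 2L * n + nxt,  0.5 * (B[, 2] - An[, 2]))   # d/d b_{i+1}.x
  put(idx, 3L * n + nxt,  0.5 * (An[, 1] - B[, 1]))   # d/d b_{i+1}.y
  put(idx, 2L * n + idx,  0.5 * (A[, 2] - Bn[, 2]))   # d/d b_i.x
  put(idx, 3L * n + idx,  0.5 * (Bn[, 1] - A[, 1]))   # d/d b_i.y
  # yolk polygon over the basal ring
  J[n + 1L, 2L * n + idx] <- 0.5 * (Bn[, 2] - Bp[, 2])
  J[n + 1L, 3L * n + idx] <- 0.5 * (Bp[, 1] - Bn[, 1])
  J
}

# Newton projection of free coordinates onto the area-constraint
# manifold; areas are quadratic in x so this converges quadratically
project_onto_constraints <- function(x, n, a_c, a_y, free, tol_abs = 1e-11,
                                     maxit = 8L) {
  for (it in seq_len(maxit)) {
    cc <- area_residuals(x, n, a_c, a_y)
    if (max(abs(cc)) < tol_abs) break
    J <- constraint_jacobian(x, n)[, free, drop = FALSE]
    M <- tcrossprod(J)
    diag(M) <- diag(M) + 1e-12
    dl <- solve(M, -cc)
    x[free] <- x[free] + drop(crossprod(J, dl))
  }
  x
}

# gradient of sum_i t[i] * A_cell_i + t_yolk * A_yolk wrt flat coords
area_weighted_grad <- function(x, n, t_cells, t_yolk) {
  .area_weighted_grad_cpp(x, as.integer(n), t_cells, t_yolk)
}

area_weighted_grad_r <- function(x, n, t_cells, t_yolk) {
  idx <- seq_len(n); nxt <- c(idx[-1], 1L); prv <- c(n, idx[-n])
  A <- cbind(x[idx], x[n + idx])
  B <- cbind(x[2 * n + idx], x[3 * n + idx])
  An <- A[nxt, , drop = FALSE]; Ap <- A[prv, , drop = FALSE]
  Bn <- B[nxt, , drop = FALSE]; Bp <- B[prv, , drop = FALSE]
  tp <- t_cells[prv]
  # cell i polygon: (a_i, a_{i+1}, b_{i+1}, b_i); vertex grad is
  # 0.5 * (next_y - prev_y, prev_x - next_x) within each polygon
  gAx <- 0.5 * (t_cells * (An[, 2] - B[, 2]) + tp * (B[, 2] - Ap[, 2]))
  gAy <- 0.5 * (t_cells * (B[, 1] - An[, 1]) + tp * (Ap[, 1] - B[, 1]))
  gBx <- 0.5 * (t_cells * (A[, 2] - Bn[, 2]) + tp * (Bp[, 2] - A[, 2]))
  gBy <- 0.5 * (t_cells * (Bn[, 1] - A[, 1]) + tp * (A[, 1] - Bp[, 1]))
  # yolk polygon over basal vertices
  gBx <- gBx + 0.5 * t_yolk * (Bn[, 2] - Bp[, 2])
  gBy <- gBy + 0.5 * t_yolk * (Bp[, 1] - Bn[, 1])
  c(gAx, gAy, gBx, gBy)
}

# reflection structure of a configuration about the DV (x) axis:
# vperm maps each vertex to the vertex its reflection lands on; ok is
# TRUE when the apical and basal rings both map within tol
mirror_map <- function(ring, tol = 1e-8) {
  refl <- function(P) cbind(P[, 1], -P[, 2])
  match_perm <- function(P) {
    R <- refl(P)
    vperm <- integer(nrow(P))
    err <- 0
    for (j in seq_len(nrow(P))) {
      d2 <- colSums((t(P) - R[j, ])^2)
      vperm[j] <- which.min(d2)
      err <- max(err, d2[vperm[j]])
    }
    list(vperm = vperm, err = sqrt(err))
  }
  a <- match_perm(ring$apical)
  b <- match_perm(ring$basal)
  ok <- a$err < tol && b$err < tol && identical(a$vperm, b$vperm) &&
    !anyDuplicated(a$vperm)
  list(ok = ok, vperm = a$vperm)
}

# TRUE if tensions and pins respect the reflection given by vperm
mirror_symmetric_problem <- function(ring, tensions, pins, vperm) {
  n <- ring$n
  nxt <- c(seq_len(n)[-1], 1L)
  cperm <- vperm[nxt]                    # cell j reflects onto cell cperm[j]
  tens_ok <- max(abs(tensions$Gamma_a - tensions$Gamma_a[cperm]),
                 abs(tensions$Gamma_b - tensions$Gamma_b[cperm]),
                 abs(tensions$Gamma_l - tensions$Gamma_l[cperm])) < 1e-12
  if (!tens_ok) return(FALSE)
  if (is.null(pins) || !length(pins$indices)) return(TRUE)
  mapped <- vperm[pins$indices]
  if (!setequal(mapped, pins$indices)) return(FALSE)
  o <- match(mapped, pins$indices)
  max(abs(pins$coords[o, 1] - pins$coords[, 1]),
      abs(pins$coords[o, 2] + pins$coords[, 2])) < 1e-8
}

# project the flat coordinate vector onto the mirror-symmetric subspace
symmetrize_state <- function(x, n, vperm) {
  idx <- seq_len(n)
  ax <- x[idx]; ay <- x[n + idx]; bx <- x[2 * n + idx]; by <- x[3 * n + idx]
  x[idx] <- (ax + ax[vperm]) / 2
  x[n + idx] <- (ay - ay[vperm]) / 2
  x[2 * n + idx] <- (bx + bx[vperm]) / 2
  x[3 * n + idx] <- (by - by[vperm]) / 2
  x
}

#' Convergence tolerances for shape minimization
#'
#' @param area maximum relative area-constraint residual.
#' @param grad projected-gradient tolerance passed to the inner
#'   quasi-Newton solver (per coordinate, augmented-Lagrangian scale).
#' @export
shape_tol <- function(area = 1e-7, grad = 5e-3) list(area = area, grad = grad)

#' Minimum-energy shape under fixed-area constraints
#'
#' Finds the configuration minimizing [total_energy()] subject to every
#' cell area equalling `A_c` and the yolk area equalling `A_y`, with
#' optional pinned apical vertices.  The `N + 1` equality constraints
#' are enforced by an augmented-Lagrangian scheme: the inner
#' unconstrained problems are solved by deterministic limited-memory
#' quasi-Newton descent (`optim` L-BFGS-B) with the analytic gradient,
#' and the multipliers are updated until the maximum relative area
#' residual falls below `tol$area`.  Runs are bit-reproducible.
#'
#' @param ring starting `embryo_ring` (also supplies the area targets).
#' @param tensions a `tension_set`.
#' @param cavity a `vitelline_cavity` or `NULL`.
#' @param pins a [pin_set()]; pinned coordinates are excluded from the
#'   optimization variables and returned bit-identical.
#' @param tol a [shape_tol()] list.
#' @param contact a [contact_params()] list or `NULL`.
#' @param control list of solver knobs: `maxit` (inner iterations,
#'   default 500), `max_outer` (multiplier updates, default 30), `mu0`
#'   (initial penalty, default 50), `mu_growth` (default 10), `warm`
#'   (multiplier state from a previous solve, for quasi-static ramps).
#' @return A list of class `shape_fit`: `ring` (relaxed), `energy`
#'   (total mechanical energy at the solution), `area_residual` (max
#'   relative), `grad_norm` (max abs augmented-Lagrangian gradient over
#'   free coordinates), `converged`, `warm` (multiplier state), and
#'   iteration counts.
#' @export
minimize_shape <- function(ring, tensions, cavity = NULL,
                           pins = NULL, tol = shape_tol(),
                           contact = contact_params(),
                           control = list()) {
  if (tensions$n != ring$n)
    stop("tension set length does not match ring size")
  n <- ring$n
  a_c <- ring$target_cell_area; a_y <- ring$target_yolk_area
  ctrl <- utils::modifyList(list(maxit = 400L, max_outer = 60L, mu = 2000,
                                 factr = 1e3, lmm = 25L, trust = 0.25,
                                 trust_max = 0.6, trust_min = 1e-4,
                                 warm = NULL),
                            control)
  x <- ring_state(ring)
  free <- rep(TRUE, 4 * n)
  if (!is.null(pins) && length(pins$indices)) {
    if (any(pins$indices < 1L | pins$indices > n)) stop("invalid pin index")
    x[pins$indices] <- pins$coords[, 1]
    x[n + pins$indices] <- pins$coords[, 2]
    free[pins$indices] <- FALSE
    free[n + pins$indices] <- FALSE
  }
  scale <- c(rep(a_c, n), a_y)
  mu <- ctrl$mu
  lambda <- if (!is.null(ctrl$warm)) ctrl$warm$lambda else numeric(n + 1L)

  # augmented-Lagrangian value/gradient with fn/gr result sharing
  cache <- new.env(parent = emptyenv())
  al_eval <- function(xf) {
    xx <- x; xx[free] <- xf
    cc <- area_residuals(xx, n, a_c, a_y)
    e <- energy_core(xx, n, tensions, cavity, contact, want_grad = TRUE)
    f <- e$W - sum(lambda * cc) + 0.5 * mu * sum(cc^2)
    g <- e$grad + area_weighted_grad(xx, n,
                                     mu * cc[seq_len(n)] - lambda[seq_len(n)],
                                     mu * cc[n + 1L] - lambda[n + 1L])
    list(f = f, g = g[free], c = cc, W = e$W)
  }
  fn <- function(xf) {
    r <- al_eval(xf)
    cache$xf <- xf; cache$g <- r$g
    r$f
  }
  gr <- function(xf) {
    if (!is.null(cache$xf) && identical(cache$xf, xf)) return(cache$g)
    al_eval(xf)$g
  }
  # projected-gradient norm on the constraint tangent space (metric only,
  # evaluated at clean feasible states)
  pg_norm <- function(x) {
    gW <- energy_core(x, n, tensions, cavity, contact, want_grad = TRUE)$grad
    J <- constraint_jacobian(x, n)[, free, drop = FALSE]
    M <- tcrossprod(J)
    diag(M) <- diag(M) * (1 + 1e-10) + 1e-12
    lam <- drop(solve(M, J %*% gW[free]))
    max(abs(gW[free] - drop(crossprod(J, lam))))
  }

  # a mirror-symmetric problem is minimized within the symmetric
  # subspace (symmetric criticality): descent then cannot amplify
  # rounding noise through symmetry-breaking soft modes.  Asymmetric
  # inputs (e.g. unilateral fixations) are detected and left free.
  mm <- mirror_map(ring_from_state(ring, x))
  sym <- mm$ok && mirror_symmetric_problem(ring, tensions, pins, mm$vperm)
  # start exactly on the constraint manifold
  x <- project_onto_constraints(x, n, a_c, a_y, free)
  if (sym)
    x <- project_onto_constraints(symmetrize_state(x, n, mm$vperm),
                                  n, a_c, a_y, free)

  inner_its <- 0L
  outer <- 0L
  converged <- FALSE
  gnorm <- pg_norm(x)
  delta <- ctrl$trust
  for (k in seq_len(ctrl$max_outer)) {
    outer <- k
    if (gnorm < tol$grad) { converged <- TRUE; break }
    # inner descent inside a per-coordinate trust box: large steps are
    # the only way a quasi-Newton line search can fold a cell through
    # itself, so displacement per sweep is capped and the cap adapted
    opt <- stats::optim(x[free], fn, gr, method = "L-BFGS-B",
                        lower = x[free] - delta, upper = x[free] + delta,
                        control = list(maxit = ctrl$maxit,
                                       factr = ctrl$factr,
                                       pgtol = 0.1 * tol$grad,
                                       lmm = ctrl$lmm))
    inner_its <- inner_its + opt$counts[["function"]]
    cc_end <- area_residuals(`[<-`(x, free, opt$par), n, a_c, a_y)
    x_try <- project_onto_constraints(`[<-`(x, free, opt$par),
                                      n, a_c, a_y, free)
    if (!all(cells_simple(ring_from_state(ring, x_try)))) {
      # fold during descent: reject the sweep, retry with a smaller box
      delta <- delta / 4
      if (delta < ctrl$trust_min)
        stop("self-intersection persists at the minimum trust step")
      next
    }
    if (sym)
      x_try <- project_onto_constraints(
        symmetrize_state(x_try, n, mm$vperm), n, a_c, a_y, free)
    moved <- max(abs(x_try[free] - x[free]))
    x <- x_try
    lambda <- lambda - mu * cc_end
    gnorm <- pg_norm(x)
    # grow the box only when it was limiting
    if (moved > 0.9 * delta) delta <- min(delta * 1.5, ctrl$trust_max)
  }

  out_ring <- ring_from_state(ring, x)
  fin <- al_eval(x[free])
  bad <- which(!cells_simple(out_ring))
  if (length(bad))
    stop("relaxation produced a self-intersecting cell polygon at cell(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         "; consider a stiffer contact repulsion or smaller ramp steps")
  structure(list(
    ring = out_ring,
    energy = fin$W,
    area_residual = max(abs(fin$c) / scale),
    grad_norm = gnorm,
    converged = converged,
    outer_iterations = outer,
    inner_evaluations = inner_its,
    warm = list(lambda = lambda, mu = mu)
  ), class = "shape_fit")
}

#' @export
print.shape_fit <- function(x, ...) {
  cat("<shape_fit> energy ", format(x$energy, digits = 8),
      ", max rel. area residual ", format(x$area_residual, digits = 3),
      ", ", if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' Quasi-static loading schedule
#'
#' The protocol that ramps apical tension in the ventral cells: `t^4`
#' time law by default, run over `n_steps` increments, ending at the
#' differential apico-basal tension `Gamma_a - Gamma_b =
#' final_differential * Gamma_l` in the (centre) ventral cell.
#'
#' @param n_steps number of quasi-static increments (default 50).
#' @param time_exponent exponent of the power-law time dependence
#'   (default 4).
#' @param final_differential final `(Gamma_a - Gamma_b)/Gamma_l` in the
#'   centre ventral cell (default 3).
#' @param spatial_profile `"step"` (all ventral cells identical) or
#'   `"graded"` (cosine-squared taper, faster increase at the centre).
#' @param graded_center_gain ratio of centre to outermost ventral
#'   increment under the graded profile (>= 1; default 2).
#' @return An object of class `ramp_schedule`.
#' @export
ramp_schedule <- function(n_steps = 50L, time_exponent = 4,
                          final_differential = 3,
                          spatial_profile = c("step", "graded"),
                          graded_center_gain = 2) {
  n_steps <- as.integer(n_steps)
  spatial_profile <- match.arg(spatial_profile)
  if (n_steps < 1L) stop("n_steps must be at least 1")
  if (final_differential < 0) stop("final_differential must be non-negative")
  if (graded_center_gain < 1) stop("graded_center_gain must be >= 1")
  structure(list(n_steps = n_steps, time_exponent = time_exponent,
                 final_differential = final_differential,
                 spatial_profile = spatial_profile,
                 graded_center_gain = graded_center_gain),
            class = "ramp_schedule")
}

#' Apical tension increments at a ramp step
#'
#' Ventral-only apical tension increments at step `step` of a
#' [ramp_schedule()]: temporal factor `(step/n_steps)^time_exponent`
#' times a spatial factor (1 for the step profile; for the graded
#' profile a symmetric cosine-squared taper, equal to 1 at the centre
#' cell and `1/graded_center_gain` at the outermost ventral cells, so
#' the centre cell always ends at the full final differential).
#'
#' @param step ramp step in `0..n_steps`.
#' @param schedule a `ramp_schedule`.
#' @param ring an `embryo_ring` (supplies the population partition).
#' @param tensions baseline `tension_set` (supplies `Gamma_l` of the
#'   ventral cells, the unit of the differential).
#' @return Per-cell apical tension increments (zero outside the ventral
#'   block).
#' @export
apical_tension_profile <- function(step, schedule, ring, tensions) {
  if (step < 0 || step > schedule$n_steps) stop("step out of range")
  n <- ring$n
  inc <- numeric(n)
  v <- which(ring$populations == "ventral")
  tfac <- (step / schedule$n_steps)^schedule$time_exponent
  if (schedule$spatial_profile == "step") {
    sfac <- rep(1, length(v))
  } else {
    g <- schedule$graded_center_gain
    ang <- angular_position(ring, v) * pi / 180
    half <- max(abs(ang))
    xrel <- if (half > 0) ang / half else ang * 0
    sfac <- (1 + (g - 1) * cos(pi * xrel / 2)^2) / g
    # normalize so the centre-most cell ends at the full differential
    # even when the block has no cell exactly on the midline
    sfac <- sfac / max(sfac)
  }
  inc[v] <- schedule$final_differential * tensions$Gamma_l[v] * tfac * sfac
  inc
}

#' Invagination branch-seeking parameters
#'
#' The energy landscape of the loaded ring is bistable near the furrow
#' transition: a shallow "constricted fan" branch coexists with the
#' deeply invaginated branch across a small barrier, and pure gradient
#' descent cannot leave the shallow branch (hysteresis of a
#' first-order-like shape transition).  After each quasi-static step
#' the ramp therefore probes the invaginated branch deterministically:
#' the ventral apical vertices are held at increasing depth (with the
#' furrow mouth narrowed by `shrink` per level) while the rest of the
#' tissue relaxes, then released and relaxed freely.  A probe is
#' accepted only if the released, unconstrained energy is lower than
#' the current branch's; if holding ever costs more than `barrier_max`
#' above the current energy the probe is abandoned (the transition is
#' not yet reachable).
#'
#' @param enable logical; probe at all.
#' @param depth_step depth increment per hold level (fraction of r_v).
#' @param max_depth deepest hold level probed (fraction of r_v).
#' @param shrink contraction of the held mouth vertices toward their
#'   centroid at each level.
#' @param barrier_max energy (tension x length units) above the current
#'   branch at which probing is abandoned.
#' @param max_stretch degeneracy guard: a probe is rejected if any
#'   apical edge of the released state exceeds this multiple of the
#'   mean resting apical edge (protects against the unphysical
#'   stiff-cell-rosette branch, see the methods vignette).
#' @param release_margin a release is only attempted once the held
#'   energy has come within this margin of the free branch's energy
#'   (releases from higher up just slide back).
#' @param min_load smallest temporal load factor `(t/n)^exponent` at
#'   which the ramp probes at all.
#' @export
seek_params <- function(enable = TRUE, depth_step = 0.1, max_depth = 0.8,
                        shrink = 0.4, barrier_max = 15, max_stretch = 6,
                        release_margin = 0.5, min_load = 0.25,
                        trace = FALSE) {
  list(enable = enable, depth_step = depth_step, max_depth = max_depth,
       shrink = shrink, barrier_max = barrier_max,
       max_stretch = max_stretch, release_margin = release_margin,
       min_load = min_load, trace = trace)
}

# reject released probe states that left the physical branch: grossly
# overstretched edges mark the degenerate stiff-cell-rosette basin
physical_state <- function(ring, cavity, max_stretch) {
  edge0 <- 2 * pi * cavity$r_v / ring$n
  max(apical_edge_lengths(ring)) < max_stretch * edge0 &&
    max(basal_edge_lengths(ring)) < max_stretch * edge0 &&
    max(lateral_edge_lengths(ring)) < 2 * sqrt(ring$target_cell_area *
                                                 max_stretch)
}

# one branch probe: hold the ventral mouth vertices on a progressively
# deeper keyhole (sac) profile, relaxing the rest, then release; accept
# only a physical released state of lower energy.  Returns a shape_fit
# or NULL.
seek_invagination <- function(cur, tensions, cavity, pins, tol, contact,
                              control, seek, energy0) {
  v <- which(cur$populations == "ventral")
  n <- cur$n
  avtx_chain <- unique(c(v, ifelse(v == n, 1L, v + 1L)))
  if (!is.null(pins) && length(intersect(avtx_chain, pins$indices)))
    return(NULL)
  if (length(avtx_chain) < 4L) return(NULL)
  ang <- atan2(cur$apical[avtx_chain, 2], cur$apical[avtx_chain, 1])
  ctr <- atan2(mean(sin(ang)), mean(cos(ang)))
  dev <- atan2(sin(ang - ctr), cos(ang - ctr))
  o <- order(dev)
  hold <- avtx_chain[o]                     # chain order across the mouth
  m <- length(hold)
  u <- c(cos(ctr), sin(ctr))
  w <- c(-u[2], u[1])
  mouth0 <- sum(apical_edge_lengths(cur)[v])  # ventral apical arc length
  d0 <- (cavity$r_v -
           min(sqrt(rowSums(apical_midpoints(cur)[v, , drop = FALSE]^2)))) /
    cavity$r_v
  held <- cur
  warm <- NULL
  k <- 0L
  repeat {
    k <- k + 1L
    d_try <- d0 + k * seek$depth_step
    if (d_try > seek$max_depth) return(NULL)
    # hairpin target: the mouth vertices line a narrow slit (two walls
    # separated by the contact gap, semicircular cap at depth d_try),
    # the shape of a ventral furrow folded apical-to-apical
    gap <- 3 * contact$range
    r_cap <- gap / 2
    r_apex <- (1 - d_try) * cavity$r_v
    r_mouth <- cavity$r_v - 0.25
    wall <- max(r_mouth - r_apex - r_cap, 0.1)
    L_path <- 2 * wall + pi * r_cap
    s <- (seq_len(m) - 1) / (m - 1) * L_path
    uu <- numeric(m); ww <- numeric(m)
    for (ii in seq_len(m)) {
      si <- s[ii]
      if (si <= wall) {                       # descending wall, lower lip
        uu[ii] <- r_mouth - si; ww[ii] <- -r_cap
      } else if (si <= wall + pi * r_cap) {   # cap around the apex
        th <- (si - wall) / r_cap             # 0..pi
        uu[ii] <- r_apex + r_cap - r_cap * sin(th)
        ww[ii] <- -r_cap * cos(th)
      } else {                                # ascending wall, upper lip
        uu[ii] <- r_mouth - (L_path - si); ww[ii] <- r_cap
      }
    }
    tgt <- cbind(uu, ww) %*% rbind(u, w)
    # sub-step the hold so no teleport exceeds ~0.4 length units
    cur_pos <- held$apical[hold, , drop = FALSE]
    nsub <- max(1L, ceiling(max(sqrt(rowSums((tgt - cur_pos)^2))) / 0.4))
    fit_h <- NULL
    for (s in seq_len(nsub)) {
      pos_s <- cur_pos + (s / nsub) * (tgt - cur_pos)
      hold_pins <- pin_set(c(hold, if (!is.null(pins)) pins$indices),
                           rbind(pos_s, if (!is.null(pins)) pins$coords))
      r0 <- held
      r0$apical[hold, ] <- pos_s
      fit_h <- tryCatch(
        minimize_shape(r0, tensions, cavity, pins = hold_pins, tol = tol,
                       contact = contact,
                       control = utils::modifyList(control,
                                                   list(warm = warm))),
        error = function(e) {
          if (isTRUE(seek$trace))
            message("seek hold failed: ", conditionMessage(e))
          NULL
        })
      if (is.null(fit_h)) return(NULL)
      held <- fit_h$ring
      warm <- fit_h$warm
    }
    if (isTRUE(seek$trace))
      message(sprintf("seek level %d: depth %.2f held dE %+.3f", k, d_try,
                      fit_h$energy - energy0))
    if (fit_h$energy > energy0 + seek$barrier_max) return(NULL)
    if (fit_h$energy > energy0 + seek$release_margin) next
    fit_r <- tryCatch(
      minimize_shape(held, tensions, cavity, pins = pins, tol = tol,
                     contact = contact, control = control),
      error = function(e) NULL)
    if (isTRUE(seek$trace) && !is.null(fit_r))
      message(sprintf("  release dE %+.3f physical %d",
                      fit_r$energy - energy0,
                      physical_state(fit_r$ring, cavity, seek$max_stretch)))
    if (!is.null(fit_r) && fit_r$energy < energy0 - 1e-8 &&
        physical_state(fit_r$ring, cavity, seek$max_stretch))
      return(fit_r)
  }
}

#' Quasi-static tension ramp
#'
#' Drives ventral apical constriction: at each of `n_steps + 1` tension
#' levels (including the unloaded baseline), the shape is re-minimized
#' with [minimize_shape()], warm-starting coordinates and constraint
#' multipliers from the previous minimum.
#'
#' @inheritParams minimize_shape
#' @param schedule a [ramp_schedule()].
#' @param seek a [seek_params()] list controlling the deterministic
#'   invagination branch probe run after each step (the loaded ring is
#'   bistable near the furrow transition and plain descent cannot cross
#'   the branch barrier).
#' @return A list of class `furrow_trajectory`: `configs` (list of
#'   `n_steps + 1` relaxed rings), `energies`, `area_residuals`,
#'   `schedule`, `tensions` (baseline), `cavity`, `pins`.
#' @export
quasi_static_ramp <- function(ring, tensions, cavity = NULL,
                              schedule = ramp_schedule(), pins = NULL,
                              tol = shape_tol(), contact = contact_params(),
                              seek = seek_params(), control = list()) {
  n_steps <- schedule$n_steps
  configs <- vector("list", n_steps + 1L)
  energies <- numeric(n_steps + 1L)
  residuals <- numeric(n_steps + 1L)
  cur <- ring
  warm <- NULL
  for (step in 0:n_steps) {
    ts <- tensions
    ts$Gamma_a <- ts$Gamma_a +
      apical_tension_profile(step, schedule, ring, tensions)
    fit <- tryCatch(
      minimize_shape(cur, ts, cavity, pins = pins, tol = tol,
                     contact = contact,
                     control = utils::modifyList(control, list(warm = warm))),
      error = function(e)
        stop("ramp failed at step ", step, ": ", conditionMessage(e)))
    if (!is.null(cavity) && isTRUE(seek$enable) && step > 0 &&
        (step / n_steps)^schedule$time_exponent >= seek$min_load) {
      alt <- seek_invagination(fit$ring, ts, cavity, pins, tol, contact,
                               control, seek, fit$energy)
      if (!is.null(alt)) fit <- alt
    }
    cur <- fit$ring
    warm <- fit$warm
    configs[[step + 1L]] <- cur
    energies[step + 1L] <- fit$energy
    residuals[step + 1L] <- fit$area_residual
  }
  structure(list(configs = configs, energies = energies,
                 area_residuals = residuals, schedule = schedule,
                 tensions = tensions, cavity = cavity, pins = pins,
                 contact = contact),
            class = "furrow_trajectory")
}

#' @export
print.furrow_trajectory <- function(x, ...) {
  cat("<furrow_trajectory> ", length(x$configs), " configurations (",
      x$schedule$n_steps, "-step ramp, final differential ",
      x$schedule$final_differential, ")\n", sep = "")
  cat("  final energy ", format(x$energies[length(x$energies)], digits = 8),
      ", max area residual ", format(max(x$area_residuals), digits = 3),
      "\n", sep = "")
  invisible(x)
}
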