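#' Per-cell surface tension set
#'
#' Holds the apical, basal and lateral surface tensions of every cell,
#' in units of the ventral cortical tension, together with the derived
#' quantities `alpha = Gamma_a/Gamma_l`, `beta = Gamma_b/Gamma_l` and
#' cortical tension `sigma = (Gamma_a + Gamma_b)/2`.
#'
#' @param Gamma_a,Gamma_b,Gamma_l apical, basal and lateral tensions;
#'   scalars or vectors of length `n`.
#' @param n number of cells (taken from the longest argument if omitted).
#' @return An object of class `tension_set`.
#' @export
tension_set <- function(Gamma_a, Gamma_b, Gamma_l, n = NULL) {
  if (is.null(n)) n <- max(length(Gamma_a), length(Gamma_b), length(Gamma_l))
  Gamma_a <- rep_len(as.numeric(Gamma_a), n)
  Gamma_b <- rep_len(as.numeric(Gamma_b), n)
  Gamma_l <- rep_len(as.numeric(Gamma_l), n)
  if (any(Gamma_l <= 0)) stop("lateral tensions must be positive")
  if (any(Gamma_a < 0) || any(Gamma_b < 0))
    stop("apical and basal tensions must be non-negative")
  structure(list(Gamma_a = Gamma_a, Gamma_b = Gamma_b, Gamma_l = Gamma_l,
                 n = n), class = "tension_set")
}

#' @export
print.tension_set <- function(x, ...) {
  cat("<tension_set> ", x$n, " cells\n", sep = "")
  s <- tension_sigma(x)
  cat("  sigma range: ", paste(format(range(s), digits = 6),
                               collapse = " .. "), "\n", sep = "")
  invisible(x)
}

#' @rdname tension_set
#' @param tensions a `tension_set`.
#' @export
tension_alpha <- function(tensions) tensions$Gamma_a / tensions$Gamma_l
#' @rdname tension_set
#' @export
tension_beta <- function(tensions) tensions$Gamma_b / tensions$Gamma_l
#' @rdname tension_set
#' @export
tension_sigma <- function(tensions) (tensions$Gamma_a + tensions$Gamma_b) / 2

#' Baseline shape ratio of the resting ring
#'
#' `alpha + beta` of the resting columnar cells: chosen so the preferred
#' single-cell height `sqrt(A_c * (alpha + beta))` equals the geometric
#' height `r_a - r_b` of the freshly built annulus, i.e. the undeformed
#' ring is the stress-free shape of its cells.
#'
#' @param ring an `embryo_ring`.
#' @return The scalar `alpha + beta` of the baseline (default ~5.66 for
#'   the 80-cell ring).
#' @export
baseline_shape_ratio <- function(ring) {
  h <- mean(lateral_edge_lengths(ring))
  h^2 / ring$target_cell_area
}

#' Population-wise tension set
#'
#' Builds a per-cell `tension_set` from per-population cortical tensions
#' `sigma`, holding the relative tensions `alpha` and `beta` fixed
#' across populations (cells of identical resting shape).  With
#' `sigma = (Gamma_a + Gamma_b)/2` and `alpha = Gamma_a/Gamma_l`,
#' `beta = Gamma_b/Gamma_l`, all three tensions of a cell scale linearly
#' with its population's `sigma`.
#'
#' @param ring an `embryo_ring`.
#' @param sigma named vector of cortical tensions with entries
#'   `ventral`, `lateral`, `dorsal` (ventral defines the tension unit).
#' @param alpha,beta relative apical and basal tensions.  The defaults
#'   (1.4 and 2.6) are the package's baseline calibration: apical-light
#'   enough that the ramped ventral apical tension can exceed the
#'   lateral cells' resting apical tension, and with a total
#'   `alpha + beta` small enough to penalize cell over-elongation yet
#'   large enough that the unloaded ring is mechanically stable for
#'   every tension parameter set (see the methods vignette).
#' @return A `tension_set` of length `ring$n`.
#' @export
population_tensions <- function(ring,
                                sigma = c(ventral = 1, lateral = 2.7,
                                          dorsal = 0.075),
                                alpha = NULL, beta = NULL) {
  if (is.null(alpha)) alpha <- 1.4
  if (is.null(beta)) beta <- 2.6
  if (alpha + beta <= 0) stop("alpha + beta must be positive")
  need <- c("ventral", "lateral", "dorsal")
  if (!all(need %in% names(sigma)))
    stop("sigma must have entries ventral, lateral, dorsal")
  pop <- as.character(ring$populations)
  key <- ifelse(pop == "ventral", "ventral",
                ifelse(pop == "dorsal", "dorsal", "lateral"))
  s <- unname(sigma[key])
  Gl <- 2 * s / (alpha + beta)
  tension_set(Gamma_a = alpha * Gl, Gamma_b = beta * Gl, Gamma_l = Gl,
              n = ring$n)
}

#' Vitelline membrane cavity
#'
#' The rigid shell enclosing the embryo, modelled as a circular cavity
#' of resting radius `r_v` that exerts the inward pressure
#' `p(r) = p_0 * (exp((r - r_v)/r_v) - 1)` on tissue beyond `r_v` and no
#' force inside (a one-sided wall: the shell cannot pull tissue
#' outward).  `p_0 = 1000` makes the shell effectively rigid; a
#' semi-hard shell (`p_0 = 10`) changes results only quantitatively.
#'
#' @param r_v resting radius (length units of `sqrt(A_c)`).
#' @param p_0 stiffness (tension unit per squared length).
#' @return An object of class `vitelline_cavity`.
#' @export
vitelline_cavity <- function(r_v, p_0 = 1000) {
  if (!is.numeric(r_v) || r_v <= 0) stop("r_v must be positive")
  if (!is.numeric(p_0) || p_0 <= 0) stop("p_0 must be positive")
  structure(list(r_v = r_v, p_0 = p_0), class = "vitelline_cavity")
}

#' Default cavity for a ring
#'
#' Resting radius set to the apical vertex radius of the freshly built
#' annulus, so the cavity initially just touches the tissue.
#'
#' @param ring an `embryo_ring`.
#' @param p_0 cavity stiffness.
#' @export
default_cavity <- function(ring, p_0 = 1000) {
  vitelline_cavity(r_v = max(sqrt(rowSums(ring$apical^2))), p_0 = p_0)
}

#' Cavity pressure and line-density potential
#'
#' `cavity_pressure` evaluates the wall pressure
#' `p(r) = p_0 * (exp((r - r_v)/r_v) - 1)` beyond the resting radius (zero
#' inside).  `cavity_potential_linedensity` is its potential per unit
#' contour length, `U(r) = p_0 * r_v * (exp((r - r_v)/r_v) - 1) -
#' p_0 * (r - r_v)` beyond the resting radius and 0 below, so that `dU/dr = p(r)`.
#'
#' @param r radial distance(s) from the embryo centre (non-negative).
#' @param cavity a `vitelline_cavity`.
#' @return Pressure, resp. energy per unit length; vectorized over `r`.
#' @export
cavity_potential_linedensity <- function(r, cavity) {
  s <- (r - cavity$r_v) / cavity$r_v
  u <- cavity$p_0 * cavity$r_v * (exp(s) - 1) - cavity$p_0 * (r - cavity$r_v)
  ifelse(r >= cavity$r_v, u, 0)
}

#' @rdname cavity_potential_linedensity
#' @export
cavity_pressure <- function(r, cavity) {
  ifelse(r >= cavity$r_v,
         cavity$p_0 * (exp((r - cavity$r_v) / cavity$r_v) - 1), 0)
}

#' Short-range contact repulsion parameters
#'
#' Quadratic repulsion between non-adjacent points of the apical surface
#' (vertices and edge midpoints) closer than `range`, preventing
#' interpenetration of the two lateral sheets when the furrow closes.
#'
#' @param range interaction range in units of `sqrt(A_c)`.
#' @param stiffness quadratic spring constant.
#' @param hinge stiffness of the cell-corner unfolding penalty: a
#'   one-sided quadratic on the signed area of each quadrilateral's four
#'   corner triangles, zero whenever every corner triangle keeps at
#'   least `hinge_margin` area and rising steeply as a corner
#'   approaches folding through itself.  A numerical guard against
#'   shear inversion during descent, not a physical energy.
#' @param hinge_margin corner-triangle signed-area threshold (in units
#'   of `A_c`) below which the guard engages.
#' @param max_extension soft ceiling on lateral (apico-basal) edge
#'   length, in units of `sqrt(A_c)`: cells cannot elongate without
#'   bound (finite membrane/cortex reservoir).  All physiological
#'   configurations stay well below the default; the ceiling exists to
#'   exclude degenerate minima in which near-tensionless cells stretch
#'   across the cavity (see the methods vignette).
#' @param max_edge the same kind of soft ceiling for apical and basal
#'   edge lengths (about 6 times the resting edge of the default ring,
#'   far above any physiological dilation).
#' @param extension_stiffness quadratic stiffness of both ceilings.
#' @export
contact_params <- function(range = 0.12, stiffness = 200, hinge = 2000,
                           hinge_margin = 0.02, max_extension = 4,
                           max_edge = 3, extension_stiffness = 10) {
  stopifnot(range >= 0, stiffness >= 0, hinge >= 0, hinge_margin >= 0,
            max_extension > 0, max_edge > 0, extension_stiffness >= 0)
  list(range = range, stiffness = stiffness, hinge = hinge,
       hinge_margin = hinge_margin, max_extension = max_extension,
       max_edge = max_edge, extension_stiffness = extension_stiffness)
}

#' Total mechanical energy of a configuration
#'
#' The tension-weighted sum of cell side lengths plus the vitelline-wall
#' potential (and, if enabled, the short-range apical contact
#' repulsion):
#' `W = sum_cells [Gamma_a * L_apical + Gamma_b * L_basal] +
#'  sum_shared lateral edges [mean(Gamma_l of the two neighbours) * L] +
#'  sum_apical edges L * U(r_mid)`.
#'
#' @param ring an `embryo_ring`.
#' @param tensions a `tension_set` of matching length.
#' @param cavity a `vitelline_cavity`, or `NULL` for no confinement.
#' @param contact a [contact_params()] list, or `NULL` to disable.
#' @return The scalar energy (tension x length units).
#' @export
total_energy <- function(ring, tensions, cavity = NULL, contact = NULL) {
  if (tensions$n != ring$n)
    stop("tension set length does not match ring size")
  if (!all(cells_simple(ring)))
    stop("non-simple cell polygon: energy undefined on degenerate geometry")
  e <- energy_core(ring_state(ring), ring$n, tensions, cavity, contact,
                   want_grad = FALSE)
  e$W
}

#' Analytic energy gradient
#'
#' Gradient of [total_energy()] with respect to all vertex coordinates,
#' in the flat order `(apical x, apical y, basal x, basal y)`.
#'
#' @inheritParams total_energy
#' @return Numeric vector of length `4 * ring$n`.
#' @export
energy_gradient <- function(ring, tensions, cavity = NULL, contact = NULL) {
  if (tensions$n != ring$n)
    stop("tension set length does not match ring size")
  energy_core(ring_state(ring), ring$n, tensions, cavity, contact,
              want_grad = TRUE)$grad
}

# flat coordinate vector <-> ring
ring_state <- function(ring) {
  c(ring$apical[, 1], ring$apical[, 2], ring$basal[, 1], ring$basal[, 2])
}
ring_from_state <- function(ring, x) {
  n <- ring$n
  ring$apical <- cbind(x[seq_len(n)], x[n + seq_len(n)])
  ring$basal <- cbind(x[2 * n + seq_len(n)], x[3 * n + seq_len(n)])
  ring
}

# chain-adjacency exclusion mask for contact pairs, cached per n.
# points are ordered (v1..vn, m1..mn); chain position of v_i is 2i-1,
# of m_i is 2i; pairs within 4 chain steps (~2 cells) do not interact.
contact_pairs_env <- new.env(parent = emptyenv())
contact_allowed <- function(n) {
  key <- as.character(n)
  if (!is.null(contact_pairs_env[[key]])) return(contact_pairs_env[[key]])
  pos <- c(2 * seq_len(n) - 1, 2 * seq_len(n))  # chain positions
  m <- 2 * n
  dpos <- abs(outer(pos, pos, "-"))
  dpos <- pmin(dpos, m - dpos)
  # only a vertex and the midpoint of its own edge are excluded: repulsion
  # between consecutive vertices doubles as an inversion guard (apical
  # spacings bottom out at ~range instead of collapsing through zero)
  allowed <- dpos >= 2
  allowed[lower.tri(allowed, diag = TRUE)] <- FALSE
  contact_pairs_env[[key]] <- allowed
  allowed
}

# Core energy/gradient engine on the flat coordinate vector.
# Returns list(W, grad); grad NULL unless want_grad.  Dispatches to the
# compiled kernel; energy_core_r is the plain-R reference used as an
# independent cross-check in the test suite.
energy_core <- function(x, n, tensions, cavity, contact, want_grad = TRUE) {
  .energy_core_cpp(x, as.integer(n),
                   tensions$Gamma_a, tensions$Gamma_b, tensions$Gamma_l,
                   !is.null(cavity),
                   if (is.null(cavity)) 1 else cavity$r_v,
                   if (is.null(cavity)) 0 else cavity$p_0,
                   !is.null(contact),
                   if (is.null(contact)) 0 else contact$range,
                   if (is.null(contact)) 0 else contact$stiffness,
                   if (is.null(contact)) 0 else contact$hinge,
                   if (is.null(contact)) 0 else contact$hinge_margin,
                   if (is.null(contact)) 1 else contact$max_extension,
                   if (is.null(contact)) 1 else contact$max_edge,
                   if (is.null(contact)) 0 else contact$extension_stiffness,
                   want_grad)
}

energy_core_r <- function(x, n, tensions, cavity, contact, want_grad = TRUE) {
  idx <- seq_len(n)
  nxt <- c(idx[-1], 1L)
  prv <- c(n, idx[-n])
  A <- cbind(x[idx], x[n + idx])
  B <- cbind(x[2 * n + idx], x[3 * n + idx])
  Ga <- tensions$Gamma_a; Gb <- tensions$Gamma_b; Gl <- tensions$Gamma_l

  gA <- if (want_grad) matrix(0, n, 2) else NULL
  gB <- if (want_grad) matrix(0, n, 2) else NULL

  # one-sided quadratic ceiling shared by all edge families
  ceil_term <- function(L) {
    if (is.null(contact) || contact$extension_stiffness <= 0)
      return(list(W = 0, dWdL = 0))
    over <- pmax(L - contact$max_edge, 0)
    list(W = 0.5 * contact$extension_stiffness * sum(over^2),
         dWdL = contact$extension_stiffness * over)
  }

  # apical edges (weight Gamma_a of the owning cell)
  Da <- A[nxt, , drop = FALSE] - A
  La <- sqrt(rowSums(Da^2))
  Ha <- Da / La
  ce <- ceil_term(La)
  W <- sum(Ga * La) + ce$W
  if (want_grad) {
    wH <- (Ga + ce$dWdL) * Ha
    gA <- gA - wH + wH[prv, , drop = FALSE]
  }

  # basal edges (weight Gamma_b)
  Db <- B[nxt, , drop = FALSE] - B
  Lb <- sqrt(rowSums(Db^2))
  Hb <- Db / Lb
  ce <- ceil_term(Lb)
  W <- W + sum(Gb * Lb) + ce$W
  if (want_grad) {
    wH <- (Gb + ce$dWdL) * Hb
    gB <- gB - wH + wH[prv, , drop = FALSE]
  }

  # lateral edges, shared: mean Gamma_l of the two adjacent cells; the
  # extension ceiling rides on the same edges
  Dl <- A - B
  Ll <- sqrt(rowSums(Dl^2))
  Hl <- Dl / Ll
  wl <- (Gl + Gl[prv]) / 2
  W <- W + sum(wl * Ll)
  dWdL <- wl
  if (!is.null(contact) && contact$extension_stiffness > 0) {
    over <- pmax(Ll - contact$max_extension, 0)
    W <- W + 0.5 * contact$extension_stiffness * sum(over^2)
    dWdL <- dWdL + contact$extension_stiffness * over
  }
  if (want_grad) {
    wH <- dWdL * Hl
    gA <- gA + wH
    gB <- gB - wH
  }

  # vitelline wall: the line-density potential integrated over each
  # apical edge by Simpson's rule (endpoints + midpoint), so no vertex
  # can escape the wall between sampling points
  if (!is.null(cavity)) {
    Uval <- function(r) {
      out <- r >= cavity$r_v
      s <- (r - cavity$r_v) / cavity$r_v
      ifelse(out, cavity$p_0 * cavity$r_v * (exp(s) - 1) -
               cavity$p_0 * (r - cavity$r_v), 0)
    }
    pval <- function(r) {
      ifelse(r >= cavity$r_v,
             cavity$p_0 * (exp((r - cavity$r_v) / cavity$r_v) - 1), 0)
    }
    M <- (A + A[nxt, , drop = FALSE]) / 2
    rm_ <- sqrt(rowSums(M^2))
    rv_ <- sqrt(rowSums(A^2))
    Um <- Uval(rm_); Uv <- Uval(rv_)
    Uavg <- (Uv + 4 * Um + Uv[nxt]) / 6
    if (any(Uavg > 0)) {
      W <- W + sum(La * Uavg)
      if (want_grad) {
        UH <- Uavg * Ha
        gA <- gA - UH + UH[prv, , drop = FALSE]
        # midpoint sample: shared between the edge's two endpoints
        Cm <- ((4 / 6) * La * pval(rm_) / rm_ / 2) * M
        gA <- gA + Cm + Cm[prv, , drop = FALSE]
        # endpoint samples: vertex i appears in edges i and i-1
        wv <- (La + La[prv]) / 6 * pval(rv_) / rv_
        gA <- gA + wv * A
      }
    }
  }

  # short-range contact repulsion between non-adjacent apical points
  if (!is.null(contact) && contact$stiffness > 0 && contact$range > 0) {
    M <- (A + A[nxt, , drop = FALSE]) / 2
    Tp <- rbind(A, M)
    sq <- rowSums(Tp^2)
    D2 <- outer(sq, sq, "+") - 2 * tcrossprod(Tp)
    close <- contact_allowed(n) & (D2 < contact$range^2)
    if (any(close)) {
      pr <- which(close, arr.ind = TRUE)
      d <- sqrt(pmax(D2[close], 1e-300))
      gap <- contact$range - d
      W <- W + 0.5 * contact$stiffness * sum(gap^2)
      if (want_grad) {
        gT <- matrix(0, 2 * n, 2)
        dir <- (Tp[pr[, 1], , drop = FALSE] - Tp[pr[, 2], , drop = FALSE]) / d
        f <- -contact$stiffness * gap * dir
        for (k in seq_len(nrow(pr))) {
          gT[pr[k, 1], ] <- gT[pr[k, 1], ] + f[k, ]
          gT[pr[k, 2], ] <- gT[pr[k, 2], ] - f[k, ]
        }
        gm <- gT[n + idx, , drop = FALSE]
        gA <- gA + gT[idx, , drop = FALSE] + 0.5 * (gm + gm[prv, , drop = FALSE])
      }
    }
  }

  # one-sided corner-unfolding guard (see contact_params)
  if (!is.null(contact) && contact$hinge > 0) {
    An <- A[nxt, , drop = FALSE]; Bn <- B[nxt, , drop = FALSE]
    # corner triangles of quad (a_i, a_{i+1}, b_{i+1}, b_i), in cyclic
    # order around each corner so all signed areas are positive when valid
    tri <- list(structure(list(B, A, An), labels = c("B", "A", "An")),
                structure(list(A, An, Bn), labels = c("A", "An", "Bn")),
                structure(list(An, Bn, B), labels = c("An", "Bn", "B")),
                structure(list(Bn, B, A), labels = c("Bn", "B", "A")))
    kap <- contact$hinge
    for (tt in tri) {
      p1 <- tt[[1]]; p2 <- tt[[2]]; p3 <- tt[[3]]
      Tk <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p2[, 2]) -
        (p2[, 2] - p1[, 2]) * (p3[, 1] - p2[, 1])
      h <- pmin(0, Tk - contact$hinge_margin)
      if (any(h < 0)) {
        W <- W + 0.5 * kap * sum(h^2)
        if (want_grad) {
          g1 <- kap * h * cbind(p2[, 2] - p3[, 2], p3[, 1] - p2[, 1])
          g2 <- kap * h * cbind(p3[, 2] - p1[, 2], p1[, 1] - p3[, 1])
          g3 <- kap * h * cbind(p1[, 2] - p2[, 2], p2[, 1] - p1[, 1])
          acc <- function(gmat, which) {
            # map triangle-corner gradients back onto A/B rows
            switch(which,
                   A  = gA <<- gA + gmat,
                   B  = gB <<- gB + gmat,
                   An = gA <<- gA + gmat[prv, , drop = FALSE],
                   Bn = gB <<- gB + gmat[prv, , drop = FALSE])
          }
          lab <- attr(tt, "labels")
          acc(g1, lab[1]); acc(g2, lab[2]); acc(g3, lab[3])
        }
      }
    }
  }

  grad <- if (want_grad) c(gA[, 1], gA[, 2], gB[, 1], gB[, 2]) else NULL
  list(W = W, grad = grad)
}

#' Preferred height of a single cell
#'
#' Minimizer of the single-cell energy
#' `e(w) = (Gamma_a + Gamma_b) * w + Gamma_l * A_c / w` at fixed cell
#' area (`w` the cell width, `h = A_c / w` its height):
#' `h_0 = sqrt(A_c * (alpha + beta))`.
#'
#' @param alpha,beta relative apical and basal tensions
#'   (`Gamma_a/Gamma_l`, `Gamma_b/Gamma_l`).
#' @param cell_area fixed cross-section area `A_c`.
#' @return The preferred height (length units).
#' @export
preferred_height <- function(alpha, beta, cell_area = 1) {
  if (any(alpha + beta <= 0)) stop("alpha + beta must be positive")
  if (any(cell_area <= 0)) stop("cell_area must be positive")
  sqrt(cell_area * (alpha + beta))
}

#' Effective Young modulus of a single cell
#'
#' Linear-response stiffness to width changes at fixed area,
#' `Y = (w*^2 / A_c) * d^2 e / dw^2` evaluated at the preferred width
#' `w* = sqrt(Gamma_l * A_c / (Gamma_a + Gamma_b))`; in closed form
#' `Y = 2 * sqrt(2 * sigma * Gamma_l / A_c)`, strictly linear in the
#' cortical tension `sigma` at fixed `(alpha, beta)`.
#'
#' @inheritParams preferred_height
#' @param sigma cortical tension `(Gamma_a + Gamma_b)/2`.
#' @return The modulus (tension / length units).
#' @export
young_modulus <- function(alpha, beta, sigma, cell_area = 1) {
  if (any(alpha + beta <= 0)) stop("alpha + beta must be positive")
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(cell_area <= 0)) stop("cell_area must be positive")
  Gl <- 2 * sigma / (alpha + beta)
  2 * sqrt(2 * sigma * Gl / cell_area)
}
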