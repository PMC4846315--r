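#' Construct the ring-of-quadrilaterals embryo cross-section
#'
#' Builds a concentric annulus of `n_cells` equal wedge-shaped
#' quadrilateral cells around an incompressible yolk, the resting
#' geometry of the 2D cross-section model.  Radii are chosen so that the
#' *polygonal* areas are exact: the basal ring is a regular
#' `n_cells`-gon enclosing exactly the target yolk area, and each cell
#' trapezoid has exactly the target cell area (the length unit is
#' `sqrt(A_c)`, i.e. `A_c = 1`).
#'
#' Cells are partitioned into four populations: a contiguous ventral
#' block centred on the ventral midline (angle 0), a contiguous dorsal
#' block centred on the dorsal midline (180 degrees), and two
#' mirror-image lateral blocks.  For the partition to be mirror
#' symmetric about the dorso-ventral axis, `n_cells` must be even and
#' `n_ventral`, `n_dorsal` must have equal parity.
#'
#' @param n_cells number of cells in the ring (even, at least 4).
#' @param n_ventral size of the ventral (constricting) block; default 10.
#' @param n_dorsal size of the dorsal block; default 20 (spanning about
#'   45 degrees either side of the dorsal midline in the default ring).
#' @param area_ratio ratio of one cell's cross-section area to the yolk
#'   cross-section area, `A_c / A_y`; default 11/600.
#' @return An object of class `embryo_ring`: a list with `apical` and
#'   `basal` (`n_cells` x 2 vertex matrices, counter-clockwise, vertex
#'   `i` and `i+1` flanking cell `i`), `n`, `populations` (factor with
#'   levels ventral, lateral_right, dorsal, lateral_left),
#'   `target_cell_area`, `target_yolk_area`.
#' @examples
#' ring <- build_ring()
#' range(cell_areas(ring))            # all exactly 1
#' yolk_area(ring) * 11 / 600         # back to 1
#' @export
build_ring <- function(n_cells = 80L, n_ventral = 10L, n_dorsal = 20L,
                       area_ratio = 11 / 600) {
  n_cells <- as.integer(n_cells)
  n_ventral <- as.integer(n_ventral)
  n_dorsal <- as.integer(n_dorsal)
  if (n_cells < 4L) stop("n_cells must be at least 4")
  if (n_cells %% 2L != 0L)
    stop("n_cells must be even (dorsal block must centre on 180 degrees)")
  if (n_ventral < 1L || n_dorsal < 1L)
    stop("n_ventral and n_dorsal must be positive")
  if (n_ventral + n_dorsal >= n_cells)
    stop("n_ventral + n_dorsal must be smaller than n_cells")
  if ((n_cells - n_ventral - n_dorsal) %% 2L != 0L)
    stop("parity violation: lateral blocks unequal ",
         "(n_cells - n_ventral - n_dorsal must be even)")
  if (!is.numeric(area_ratio) || area_ratio <= 0)
    stop("area_ratio must be positive")

  a_c <- 1
  a_y <- a_c / area_ratio
  theta <- 2 * pi / n_cells
  # polygonal areas exact: regular n-gon for the yolk, trapezoids for cells
  r_b <- sqrt(2 * a_y / (n_cells * sin(theta)))
  r_a <- sqrt(r_b^2 + 2 * a_c / sin(theta))

  # cell i is centred at angle (i - 1) * theta + delta; a vertex (even
  # n_ventral) or a cell centre (odd n_ventral) sits on the ventral midline
  delta <- if (n_ventral %% 2L == 0L) theta / 2 else 0
  centres <- (seq_len(n_cells) - 1L) * theta + delta
  phi <- centres - theta / 2             # vertex i leads cell i
  phi <- atan2(sin(phi), cos(phi))
  apical <- cbind(r_a * cos(phi), r_a * sin(phi))
  basal <- cbind(r_b * cos(phi), r_b * sin(phi))
  # make the ring mirror symmetric about the DV axis to the last bit:
  # vertices with negative angle are the exact reflections of their
  # positive-angle partners, so deterministic descent cannot seed
  # left-right asymmetry from rounding
  onaxis <- abs(sin(phi)) < 1e-9
  apical[onaxis, 2] <- 0
  basal[onaxis, 2] <- 0
  neg <- which(phi < -1e-12 & !onaxis)
  for (j in neg) {
    jm <- which.min(abs(phi + phi[j]))
    apical[j, ] <- c(apical[jm, 1], -apical[jm, 2])
    basal[j, ] <- c(basal[jm, 1], -basal[jm, 2])
  }

  populations <- assign_populations(centres, n_ventral, n_dorsal)

  ring <- structure(list(
    apical = apical, basal = basal, n = n_cells,
    populations = populations,
    target_cell_area = a_c, target_yolk_area = a_y
  ), class = "embryo_ring")
  validate_ring(ring)
  ring
}

# population labels from cell-centre angles; blocks are contiguous and
# centred on the ventral (0) and dorsal (pi) midlines
assign_populations <- function(centres, n_ventral, n_dorsal) {
  n <- length(centres)
  wrap <- function(a) atan2(sin(a), cos(a))
  d_ventral <- abs(wrap(centres))
  d_dorsal <- abs(wrap(centres - pi))
  pop <- rep("lateral_right", n)
  pop[order(d_ventral)[seq_len(n_ventral)]] <- "ventral"
  pop[order(d_dorsal)[seq_len(n_dorsal)]] <- "dorsal"
  lat <- pop %in% c("lateral_right")
  pop[lat & wrap(centres) < 0] <- "lateral_left"
  factor(pop, levels = c("ventral", "lateral_right", "dorsal", "lateral_left"))
}

#' Indices of the four cell populations
#'
#' @param ring an `embryo_ring`.
#' @return A list with components `ventral`, `lateral_left`,
#'   `lateral_right`, `dorsal`, each an integer index vector; together
#'   they cover all cells exactly once.
#' @export
population_map <- function(ring) {
  p <- ring$populations
  list(
    ventral = which(p == "ventral"),
    lateral_left = which(p == "lateral_left"),
    lateral_right = which(p == "lateral_right"),
    dorsal = which(p == "dorsal")
  )
}

#' Signed polygon area (shoelace formula)
#'
#' @param points an m x 2 matrix of vertices in order; m >= 3.
#' @return The signed area: positive for counter-clockwise orientation.
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # +1
#' @export
polygon_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("a polygon needs at least 3 points")
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# vertex matrix of cell i: (apical i, apical i+1, basal i+1, basal i)
cell_polygon <- function(ring, i) {
  j <- if (i == ring$n) 1L else i + 1L
  rbind(ring$apical[i, ], ring$apical[j, ], ring$basal[j, ], ring$basal[i, ])
}

#' Per-cell polygon areas
#' @param ring an `embryo_ring`.
#' @return Numeric vector of signed cell areas (positive when valid).
#' @export
cell_areas <- function(ring) {
  a <- ring$apical; b <- ring$basal
  nxt <- c(seq_len(ring$n)[-1], 1L)
  cross2 <- function(u, v) u[, 1] * v[, 2] - u[, 2] * v[, 1]
  an <- a[nxt, , drop = FALSE]; bn <- b[nxt, , drop = FALSE]
  (cross2(a, an) + cross2(an, bn) + cross2(bn, b) + cross2(b, a)) / 2
}

#' Yolk (basal polygon) area
#' @param ring an `embryo_ring`.
#' @return Signed area enclosed by the basal vertex ring.
#' @export
yolk_area <- function(ring) polygon_area(ring$basal)

#' Angular position of a cell
#'
#' Angle of the cell's apical edge midpoint in the model convention:
#' 0 degrees at the ventral midline, +/-180 degrees at the dorsal
#' midline, positive toward the right lateral side.
#'
#' @param ring an `embryo_ring`.
#' @param cell_index cell index (1-based), vectorized.
#' @return Angle(s) in degrees in (-180, 180].
#' @export
angular_position <- function(ring, cell_index) {
  if (any(cell_index < 1L | cell_index > ring$n)) stop("invalid cell index")
  m <- apical_midpoints(ring)[cell_index, , drop = FALSE]
  deg <- atan2(m[, 2], m[, 1]) * 180 / pi
  ifelse(deg <= -180, deg + 360, deg)
}

# midpoints of apical edges, one row per cell
apical_midpoints <- function(ring) {
  nxt <- c(seq_len(ring$n)[-1], 1L)
  (ring$apical + ring$apical[nxt, , drop = FALSE]) / 2
}

# lengths of the three edge families, one value per cell / per shared edge
apical_edge_lengths <- function(ring) {
  nxt <- c(seq_len(ring$n)[-1], 1L)
  d <- ring$apical[nxt, , drop = FALSE] - ring$apical
  sqrt(rowSums(d^2))
}
basal_edge_lengths <- function(ring) {
  nxt <- c(seq_len(ring$n)[-1], 1L)
  d <- ring$basal[nxt, , drop = FALSE] - ring$basal
  sqrt(rowSums(d^2))
}
# lateral edge i joins apical i and basal i (shared by cells i-1 and i)
lateral_edge_lengths <- function(ring) {
  d <- ring$apical - ring$basal
  sqrt(rowSums(d^2))
}

# TRUE per cell if its quadrilateral is simple (no opposite edges cross)
# and positively oriented
cells_simple <- function(ring) {
  n <- ring$n
  nxt <- c(seq_len(n)[-1], 1L)
  a <- ring$apical; an <- a[nxt, , drop = FALSE]
  b <- ring$basal; bn <- b[nxt, , drop = FALSE]
  # quad (a, an, bn, b): opposite edge pairs (a-an, bn-b) and (an-bn, b-a)
  ok1 <- !segments_intersect(a, an, bn, b)
  ok2 <- !segments_intersect(an, bn, b, a)
  ok1 & ok2 & (cell_areas(ring) > 0)
}

# vectorized proper-intersection test for segment pairs (p1,p2) x (q1,q2)
segments_intersect <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
      (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
  }
  d1 <- orient(q1, q2, p1); d2 <- orient(q1, q2, p2)
  d3 <- orient(p1, p2, q1); d4 <- orient(p1, p2, q2)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Validate an embryo ring
#'
#' Checks the structural invariants: matching vertex counts, simple
#' positively oriented cell quadrilaterals, basal polygon enclosing the
#' origin, population labels covering every cell.
#'
#' @param ring an `embryo_ring`.
#' @return The ring, invisibly; stops with a diagnostic on violation.
#' @export
validate_ring <- function(ring) {
  stopifnot(inherits(ring, "embryo_ring"))
  if (nrow(ring$apical) != ring$n || nrow(ring$basal) != ring$n)
    stop("apical and basal vertex counts must both equal n")
  if (length(ring$populations) != ring$n)
    stop("population labels must cover all cells")
  if (yolk_area(ring) <= 0)
    stop("basal polygon must be positively oriented")
  bad <- which(!cells_simple(ring))
  if (length(bad))
    stop("cell polygon self-intersects or is inverted at cell(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  # winding of the basal polygon about the origin
  ang <- atan2(ring$basal[, 2], ring$basal[, 1])
  w <- sum(atan2(sin(diff(c(ang, ang[1]))), cos(diff(c(ang, ang[1])))))
  if (abs(w - 2 * pi) > 1e-6)
    stop("basal polygon must wind once around the origin")
  invisible(ring)
}

#' @export
print.embryo_ring <- function(x, ...) {
  cnt <- table(x$populations)
  cat("<embryo_ring> ", x$n, " cells (",
      paste(names(cnt), cnt, sep = ":", collapse = ", "), ")\n", sep = "")
  cat("  target areas: cell ", format(x$target_cell_area),
      ", yolk ", format(x$target_yolk_area), "\n", sep = "")
  cat("  apical radius range: ",
      paste(format(range(sqrt(rowSums(x$apical^2))), digits = 6),
            collapse = " .. "), "\n", sep = "")
  invisible(x)
}

#' Plot an embryo cross-section
#'
#' Draws the cell quadrilaterals coloured by population; intended for
#' quick inspection of relaxed or mid-ramp configurations.
#'
#' @param x an `embryo_ring`.
#' @param cavity optional `vitelline_cavity`; its resting circle is drawn.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot.embryo_ring <- function(x, cavity = NULL, main = "", ...) {
  r <- max(sqrt(rowSums(x$apical^2)))
  if (!is.null(cavity)) r <- max(r, cavity$r_v)
  graphics::plot(NA, xlim = c(-r, r) * 1.05, ylim = c(-r, r) * 1.05,
                 asp = 1, xlab = "x / sqrt(A_c)", ylab = "y / sqrt(A_c)",
                 main = main, ...)
  cols <- c(ventral = "#c0392b", lateral_right = "#2980b9",
            dorsal = "#27ae60", lateral_left = "#8e44ad")
  for (i in seq_len(x$n)) {
    p <- cell_polygon(x, i)
    graphics::polygon(p[, 1], p[, 2],
                      col = grDevices::adjustcolor(
                        cols[[as.character(x$populations[i])]], 0.5),
                      border = "grey25", lwd = 0.4)
  }
  if (!is.null(cavity)) {
    t <- seq(0, 2 * pi, length.out = 256)
    graphics::lines(cavity$r_v * cos(t), cavity$r_v * sin(t),
                    lty = 2, col = "grey40")
  }
  invisible(x)
}
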