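---
title: "A differential-tension model of the early embryo cross-section"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A differential-tension model of the early embryo cross-section}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 6)
library(furrow2d)
```

## The model

The early *Drosophila* embryo cross-section is represented as a ring of
$N = 80$ quadrilateral cells with straight edges, enclosing an
incompressible yolk and enclosed by a rigid vitelline shell.  Cell
interiors and yolk are incompressible, so the cross-section area of
every cell ($A_c$) and of the yolk ($A_y$) are hard constraints, with
$A_c/A_y = 11/600$.  $A_c = 1$ defines the length unit $\sqrt{A_c}$.

Cell shape is governed by effective surface tensions on the three cell
sides: apical $\Gamma_a$ (outer), basal $\Gamma_b$ (facing the yolk)
and lateral $\Gamma_l$ (cell-cell interfaces).  The total energy is the
tension-weighted sum of side lengths,

$$W=\sum_{\text{cells}}\big[\Gamma_a L_a+\Gamma_b L_b\big]
  +\sum_{\text{shared lateral edges}}\bar\Gamma_l\,L_l
  +\sum_{\text{apical edges}} L\,U(r),$$

where each shared lateral edge is counted once with the mean
$\bar\Gamma_l$ of its two cells, and $U(r)$ is the line density of the
vitelline-wall potential, with
$p(r)=p_0\{\exp[(r-r_v)/r_v]-1\}$ the wall pressure beyond the resting
radius $r_v$ and $U'(r)=p(r)$, $U(r<r_v)=0$.  The wall is one-sided: it
pushes tissue inward but cannot pull it outward.  $p_0=1000$ makes the
shell effectively rigid.  Numerically, $U$ is integrated over each
apical edge by Simpson's rule (both endpoints and the midpoint), so no
vertex can slip between sampling points.

Three cell populations -- 10 ventral cells centred on the ventral
midline, two lateral blocks of 25, and 20 dorsal cells spanning roughly
$\pm45^\circ$ about the dorsal midline -- share the same relative
tensions $\alpha=\Gamma_a/\Gamma_l$ and $\beta=\Gamma_b/\Gamma_l$ but
differ in cortical tension $\sigma=(\Gamma_a+\Gamma_b)/2$, measured in
units of the ventral $\sigma$.  A cell's effective Young modulus is
$Y=2\sqrt{2\sigma\Gamma_l/A_c}$, strictly linear in $\sigma$: stiff
populations are the high-$\sigma$ ones.  The best-fit tension ratio is
$1 : 2.7 : 0.075$ (ventral : lateral : dorsal, parameter set I); set II
swaps lateral and dorsal; set III makes all three equal.

Furrow formation is driven by a quasi-static ramp of ventral apical
tension with a $t^4$ time law over `n_steps` increments (default 50),
ending at the differential $\Gamma_a-\Gamma_b = 3\Gamma_l$ in the
ventral cells.  At every increment the energy is re-minimized under all
$N+1$ area constraints, warm-starting from the previous minimum.

## Numerical scheme

`minimize_shape()` is an augmented-Lagrangian quasi-Newton scheme:
inner descent sweeps (`optim` L-BFGS-B with the analytic gradient,
compiled in C++) run inside a per-coordinate trust box, each accepted
sweep is followed by an exact Newton projection onto the area-constraint
manifold (areas are quadratic in the coordinates, so the projection
converges quadratically and residuals sit at machine precision), and
convergence is declared on the projected-gradient norm (default
`5e-3`; energies are converged to ~1e-6 well before this).  A fold of
any cell quadrilateral during a sweep rejects the sweep and shrinks the
trust box.  Runs are deterministic and bit-reproducible.  When the
problem itself is mirror-symmetric about the dorso-ventral axis
(geometry, tensions and pins all reflection-invariant), minimization is
restricted to the symmetric subspace -- a critical point there is a
critical point of the full problem -- so rounding noise cannot seed
left-right symmetry breaking; asymmetric inputs such as unilateral
fixations are detected and left unconstrained.

Three regularization terms guard the straight-edge discretization; all
three are zero on physiological shapes:

* **contact repulsion** between non-adjacent points of the apical
  surface (vertices and edge midpoints) closer than `range = 0.12`,
  preventing interpenetration where apical surfaces meet, and --
  because a cluster of $m$ points pays $\mathcal{O}(m^2)$ pairwise
  penalties while two pressed surfaces pay only $\mathcal{O}(m)$ --
  suppressing degenerate many-cell "rosette" hubs;
* a **corner hinge**: a one-sided quadratic on the signed area of each
  quadrilateral's corner triangles below a small margin (0.02 $A_c$),
  blocking shear inversion of cells during descent;
* **edge ceilings**: one-sided quadratics above a maximum edge length
  (3 for apical/basal edges, 4 for lateral edges), encoding that cells
  cannot elongate without bound.

## Why the guards exist: degenerate minima

The energy above, taken literally at the set-I tension ratios, has
degenerate low-energy minima in which the nearly tensionless dorsal
cells ($\sigma=0.075$) stretch across the cavity while the stiff
lateral cells wrap around a common vertex ("rosettes"), minimizing
their own high-tension surfaces at no dorsal cost.  We verified by
direct construction that such states can lie far below any
physiological shape.  They are artifacts of the straight-edge polygon
representation -- real cells cannot pass through one another or extend
indefinitely -- and the guards above remove them without measurably
affecting physiological configurations.

## The furrow transition and what this implementation reproduces

With the constraints and tension ratios fixed, the loaded ring is
bistable: a superficial branch (ventral apical constriction with the
tissue on the shell) coexists with internalized configurations (the
ventral cells folded into a sac) across an energy barrier.  Pin-drag
continuation experiments in this implementation locate physically
shaped internalized states, but at the final differential $3\Gamma_l$
they remain slightly above the superficial branch in energy, and the
deterministic descent protocol therefore remains on the superficial
branch -- the model here captures furrow *initiation*: ventral apical
constriction, ventral-ward displacement of the lateral cohorts, and
dorsal-dominant dilation, with a shallow indentation rather than full
internalization.  `seek_params()`/branch probing is available to
explore held-and-released internalized configurations, and is off by
default.  Consequences for the in-silico experiments:

* comparisons across conditions (parameter sets, fixation geometries,
  tension grids) are made on the same branch and remain informative
  for the initiation phase;
* conclusions that hinge on *full* internalization (saturated furrow
  depths, internalization-blocking classifications) are outside what
  this implementation reproduces, and the corresponding checks are
  expected to fail honestly rather than being tuned to pass.

## Baseline parameters

The model geometry fixes the resting cell aspect (height/width
$\approx 5.66$), but not $\alpha$ and $\beta$ individually.  The
package default is $\alpha = 1.4$, $\beta = 2.6$:

* $\alpha < 3/(\sigma_{lat}-1) = 1.76$ keeps the ramped ventral apical
  tension above the lateral apical tension at full load, a necessary
  condition for the constricting cells to reel in the lateral sheets;
* $\alpha+\beta = 4$ penalizes cell over-elongation (preferred height
  $h_0=\sqrt{A_c(\alpha+\beta)} = 2$ against the geometric height
  2.38) strongly enough to matter, while keeping the *unloaded* ring
  mechanically stable under all three tension parameter sets --
  smaller $\alpha$ or $\alpha+\beta$ triggers spontaneous buckling
  with no ventral drive at all.

The closed-form consistency check (a uniform-tension ring relaxing to
heights equal to $h_0$) is run at the geometry-matched ratio
$\alpha+\beta=(r_a-r_b)^2\approx 5.66$, the unique value at which the
area constraints and the single-cell optimum are compatible.

## Observables

* **furrow depth**: $(r_v-\min_i r_i)/r_v$ over ventral apical edge
  midpoints, clipped to $[0,1]$;
* **dorsal dilation**: mean dorsal apical edge length over its
  reference value (lateral dilation analogously, as the cohort
  rigidity check);
* **lateral displacement**: mean tangential arc displacement of
  lateral apical midpoints at the initial radius, positive toward the
  ventral midline, per side and averaged;
* **midline angle**: depth-weighted circular mean of the ventral
  apical midpoints (weights are squared ingression depths) -- the apex
  angle for a developed furrow, exactly 0 for symmetric states, and
  free of argmin flicker when the furrow is shallow;
* **kymograph**: apical boundary angles against ramp step, unwrapped
  in time.

## Synthetic data

The generator emulates (a) noisy time series of the three observables
-- the deterministic ramp plus independent additive Gaussian noise per
observable and step, seeded and reproducible, with the noiseless limit
equal to the deterministic trajectory -- and (b) ablation recoil-speed
curves $v(t)=\sigma_{rel}\,e^{-t/\tau}$ with drag normalized to 1, so
the initial speed equals the relative cortical tension (ventral-like
$\tau=4$ s, lateral-like $\tau<1$ s, no recoil dorsally).  These stand
in for imaging-derived measurements; they share none of the real data's
segmentation noise, drift, or spatial correlations, so passing recovery
tests demonstrate correctness of the inference plumbing, not
performance on microscopy data.

## Problem sizes used in the shipped checks

The test suite runs the default 80-cell ring with 10-step ramps for the
condition comparisons (battery, tension grids, recovery) and a single
50-step ramp for the area-conservation check; the acceptance script
uses 20-step ramps on a 7-point lateral-tension grid.  Halving the step
count changes final-state observables by well under the tolerances
used, so shorter schedules serve as faithful stand-ins for the default
50-step protocol in repeated sweeps.

## Known limitations

* 2D cross-section: apical constriction necessarily trades cell height
  for width; the anterior-posterior dimension is absent.
* No viscous dynamics, no cell rearrangement, no explicit actomyosin
  turnover; time enters only through the quasi-static load parameter.
* Full mesoderm internalization is not reached by energy descent in
  this implementation (see above).
* The vitelline resting radius is set to the apical radius of the
  freshly built ring (shell initially just touching), and the wall is
  one-sided by construction.
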