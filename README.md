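# furrow2d

Mechanics of ventral furrow formation in the early *Drosophila* embryo,
modelled on its 2D cross-section: a ring of N = 80 quadrilateral cells
around an incompressible yolk, confined by a rigid vitelline shell, with
cell shape set by apical, basal and lateral surface tensions under hard
area constraints.  The package is aimed at tissue-mechanics modellers
who want a tested, scriptable re-implementation of this class of
differential-tension vertex models, including its in-silico experiments.

The total energy is the tension-weighted sum of cell side lengths plus a
one-sided wall potential with pressure
`p(r) = p0 {exp[(r - rv)/rv] - 1}` beyond the shell's resting radius;
every cell area and the yolk area are exact constraints.  Three cell
populations (10 ventral, 2 x 25 lateral, 20 dorsal cells) share the
relative tensions `alpha = Ga/Gl` and `beta = Gb/Gl` but differ in
cortical tension `sigma = (Ga + Gb)/2` (ventral = 1 defines the unit;
the best-fit ratio is 1 : 2.7 : 0.075 ventral : lateral : dorsal).  A
cell's effective Young modulus is `Y = 2 sqrt(2 sigma Gl / Ac)`, linear
in `sigma`.  Furrow formation is driven by a quasi-static `t^4` ramp of
ventral apical tension to the final differential `Ga - Gb = 3 Gl`, with
full constrained energy re-minimization at every increment
(augmented-Lagrangian quasi-Newton descent with exact Newton projection
onto the area constraints; deterministic and bit-reproducible).

See `vignette("differential-tension-model")` for the model's
assumptions, the numerical guards, the baseline-parameter calibration,
and what this implementation does and does not reproduce (in brief: it
captures furrow initiation -- ventral apical constriction, cohort-like
lateral displacement, dorsal-dominant dilation -- while full mesoderm
internalization is not reached by plain energy descent in this energy;
the deep branch remains metastable-above the superficial one).

## Worked example

```r
library(furrow2d)

ring    <- build_ring()                      # 80 cells, Ac/Ay = 11/600
cavity  <- default_cavity(ring)              # rigid shell, p0 = 1000
tension <- population_tensions(ring)         # set I: 1 : 2.7 : 0.075
traj    <- quasi_static_ramp(ring, tension, cavity,
                             ramp_schedule(n_steps = 10))

fin <- traj$configs[[11]]
observable_set(fin, traj$configs[[1]], cavity)
#>   furrow_depth dorsal_dilation lateral_displacement midline_angle lateral_dilation
#> 1       0.0081          1.1764               0.6509             0           1.0315
```

Read: after the ramp the ventral apical surface has constricted (a
shallow indentation of 0.8% of the shell radius), the lateral sheets
have moved 0.65 cell widths toward the ventral midline while stretching
only 3% (cohort motion), the dorsal tissue has dilated 18% -- dorsal
dilation exceeding lateral dilation is the signature of the
differential-tension regime -- and the furrow sits exactly on the
midline (angle 0).

`plot(fin, cavity)` draws the cross-section.  Other entry points:
`phase_diagram()` (tension sweeps with the best-fit mask),
`cauterization_battery()` (the six fixation experiments),
`isolation_test()`, `fit_tensions()` (grid inference from observables),
`tensions_from_recoil()` (ablation readout), and the seeded
synthetic-data generators `gen_observable_track()` /
`gen_recoil_curve()`.  A thin command-line driver with the same verbs
is installed as `exec/furrow2d`.

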