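---
title: "Evolutionary quadric reconstruction of corneal surfaces: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary quadric reconstruction of corneal surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the surface model
and the two error functionals, the evolutionary fitter and its constraint
handling, the classical baselines, the morphometric transform, what the
synthetic generator does and does not emulate, and the numerical decisions
a maintainer would want written down.

## The measurement and its discretization

A Scheimpflug tomographer samples each corneal surface on a polar grid:
rings at radii $r_i = i \cdot 0.2$ mm ($i = 1,\dots,24$, so the aperture
spans 0.2–4.8 mm) crossed with semi-meridians at
$\theta_j = (j-1)\,2\pi/256$ — 6144 nodes per surface. Elevations are
absolute $z$ values in mm; a cell the instrument could not measure holds
the sentinel value $-1000.0$ exactly, which is part of the CSV format
contract and is compared with `==` on purpose. `polar_to_cartesian()` maps
each valid cell to $(r_i\cos\theta_j,\; r_i\sin\theta_j,\; z_{ij})$ and
eliminates sentinels; nothing is interpolated. Column 1 sits at angle 0,
counter-clockwise, right-handed axes, $z$ along the instrument axis — the
angular zero offset is a convention (the export format does not pin it)
and only relabels meridians. Because vendor CSV layouts vary, the
delimiter, orientation, grid size and ring spacing are all carried by a
`polar_grid_dialect()` object rather than hard-coded; the written format
uses 17 significant digits so a write/read cycle reproduces the elevation
matrix bit for bit.

## Surface model and the two error functionals

The corneal cap is modelled as a single implicit quadric
$$Q(\mathbf p) = \mathbf p^\top A \mathbf p + \mathbf b^\top \mathbf p + k,$$
ten coefficients stored in the fixed order
`a11, a12, a13, a10, a22, a23, a20, a33, a30, a00`. Two distinct
functionals are kept deliberately separate:

* the **algebraic fitness** $(1/N)\sum_s Q(P_s)^2$ — smooth and cheap,
  the objective every fitter minimizes;
* the **elevation MSE** $(1/N')\sum_s (\hat z_s - z_s)^2$ — the reported
  goodness of fit, where $\hat z_s$ solves $Q(x_s, y_s, z) = 0$ at the
  acquisition node and $N'$ counts nodes with a real root.

The algebraic problem is scale-degenerate ($\mathbf a = 0$ is a global
minimizer), so all fitting is done under $\lVert \mathbf a \rVert_2 = 1$,
enforced by projection after every update rather than by pinning
$a_{11} = 1$: pinning a coefficient biases the accessible shape family,
while the unit sphere treats all ten directions symmetrically. (The
$a_{11} = 1$ convention remains available in the least-squares baseline as
`constrain_a11 = TRUE`.) The sign is canonicalized so $a_{33} \ge 0$,
falling through to the first nonzero second-order coefficient.

Nodes where the fitted surface has no real elevation are excluded from
the MSE average but counted and reported (`unresolved`); an MSE over zero
resolvable nodes is an error, not a number.

**Preconditioning.** Quadric scatter matrices in raw mm units are
severely ill-conditioned (monomials spanning $10^{-2}$–$10^1$). Every
fitter centers the cloud on its centroid, scales the largest centroid
distance to 1, fits in those coordinates, and maps the coefficients back
through the exact affine transform of the quadratic form. This is purely
a conditioning device; reported coefficients and errors always live in
instrument coordinates.

## The evolutionary fitter

`fit_nsmvga()` is an elitist, real-coded, multivariable genetic algorithm
over the ten (preconditioned) coefficients. Defaults follow the method's
published configuration and are not tuned per dataset:

| parameter | default | meaning |
|---|---|---|
| `pop_per_variable` | 100 | 10 variables → 1000 individuals/generation |
| `crossover_rate` | 0.8 | fraction of offspring from blend crossover |
| `survival_rate` | 0.2 | elites cloned unchanged |
| `mutation_rate` | 0 | published setting; nonzero available |
| `function_tolerance` | 1e-50 | stall-improvement threshold, taken literally |
| `max_generations` / `stall_generations` | 300 / 50 | termination guarantees |
| `gene_bounds` | [−1, 1] | in preconditioned coordinates |
| `blend_alpha` | 0.5 | BLX-α expansion |

Selection is size-2 tournament; crossover is BLX-α (offspring gene
uniform on the parents' interval expanded by α on each side), then
clipping to the gene bounds and projection back to the unit sphere.
Elites guarantee the best fitness is monotone non-increasing — asserted
in the tests on every run. A tolerance of $10^{-50}$ is below what double
precision can distinguish, so termination is additionally guaranteed by
the stall window (no improvement above tolerance across 50 generations —
in practice this fires when the population has collapsed to one genotype)
and the generation cap. All randomness flows from `config$seed`; a run is
bit-reproducible.

**Constraint handling (feasibility ranking).** The unit norm is the only
*equality* constraint, handled by projection. But a corneal
reconstruction must additionally be a usable second-order surface: an
ellipsoid-signature quadratic form that actually covers the measured
columns. These validity constraints are handled the way constrained
evolutionary algorithms rank feasibility: an individual whose quadratic
form is not (positive- or negative-) definite — checked in closed form
via Sylvester's criterion, vectorized over the population — or whose
surface misses sampled data columns, has $(2\,\Delta z)^2$ added per
violation ($\Delta z$ = elevation range), which places every infeasible
individual below every feasible one while preserving fitness order within
each class. This matters in practice: on clouds whose outer rings are
missing, a hyperboloid is a genuine local basin of the unconstrained
algebraic problem, and a mutation-free GA that wanders into it cannot
leave. With feasibility ranking the fitter returns a valid ellipsoid
whenever one fits, which is what the zero-failure property (FQN = 0)
measured in the acceptance tests rests on. When no candidate is ever
feasible — data that genuinely admit no ellipsoid — the penalty is a
constant offset, ranking degrades gracefully to plain fitness, and the
failure is reported honestly through `fq = 1`.

The column-coverage check inside the GA loop runs on a fixed coarse
subsample of nodes (default 384, deterministic stride) scaled to the full
cloud — a numerical economy only; the *reported* MSE and unresolved count
are always computed on all nodes. The algebraic fitness itself is exact
at any population size via the identity
$(1/N)\sum_s Q(P_s)^2 = \mathbf a^\top M \mathbf a$ with
$M = D^\top D / N$ precomputed once ($D$ the $N \times 10$ monomial
design matrix).

`warm_start = TRUE` seeds the population around the direct linear
solution; it is off by default so that the evolutionary search itself is
what is exercised and tested.

**Terminal precision.** With zero mutation the population ultimately
fixates: once all genotypes coincide, blend crossover reproduces them
exactly and evolution stops. On noisy data this is irrelevant — the fit
reaches the noise floor long before fixation (the acceptance runs recover
radii to ≪ 1 % at 5 µm noise). On *noiseless* data the GA lands around
$10^{-16}$ mm² elevation MSE, a dozen orders below any clinical signal
but far above the $\sim 10^{-31}$ rounding floor that the closed-form
direct solver attains; an evolutionary search cannot track an arbitrarily
rotated null direction to machine precision with axis-aligned crossover
alone. The acceptance suite states this comparison at its face-value
threshold and the corresponding check documents the gap rather than
hiding it; every other criterion is met with margin.

## Classical baselines

* `fit_direct_linear()` — the exact minimizer of the norm-constrained
  algebraic problem: the right singular vector of $D$ for the smallest
  singular value. Deterministic; the oracle all other fitters are tested
  against. A design with more than one vanishing singular value
  (coplanar or otherwise degenerate clouds) is rejected as degenerate
  (threshold: $\sigma_9 < 10^{-10}\,\sigma_1$).
* `fit_lsq_trra()` — weighted least squares by damped trust-region
  Gauss–Newton (Levenberg–Marquardt), from a neutral 7.8 mm sphere
  centered on the cloud axis (a clinically typical anterior radius makes
  the baseline reproducible without per-case tuning). The Jacobian is
  supplied analytically — the residuals are linear in the coefficients —
  because finite differencing cannot resolve this ill-conditioned design
  and stalls orders of magnitude short of the optimum. Weights are
  uniform by default; `weights = "radial"` down-weights the noisier
  periphery as $1/(1 + (r/r_{\max})^2)$.
* `fit_sqp()` — sequential quadratic programming on the equality-
  constrained problem, i.e. damped Lagrange–Newton iteration on the KKT
  system (for a quadratic objective with one quadratic constraint the SQP
  subproblem *is* the Newton step). Every KKT point of this problem is an
  eigenpair of $M$, so from unlucky starts SQP can settle on saddles —
  the known instability of local methods on deformed or truncated
  clouds. Such outcomes are flagged (`converged`, `fq`), never patched.

## Morphometrics

`to_canonical_ellipsoid()` eigen-decomposes $A$, translates to the
quadric center ($2At = -\mathbf b$), verifies the ellipsoid signature
(eigenvalues of one sign, centered constant of the opposite sign), and
assigns axes: the eigenvector with the largest $|z|$ component is the
optical ($c$) axis — the tomographer's axis is the only physically
distinguished direction — and of the remaining two, the larger $|x|$
component becomes the $a$ axis; signs are chosen right-handed. The
clinical parameters follow as $R_x = a^2/c$, $Q_x = (a/c)^2 - 1$ (and
analogously in $y$); the asphericity definition is the one consistent
with the apical-radius formula through the conicoid meridian identity
$r^2 = 2Rs - (1+Q)s^2$, which the tests verify symbolically against the
ellipsoid section. Both meridians are always reported; users wanting a
single "anterior radius of curvature" can average them, and the
comparison tables keep them separate precisely so that that choice stays
with the analyst.

`check_quadric_order()` returns the failure flag `fq`: 1 when the
second-order block has numerically vanished (norm < 10⁻⁶ on the
unit-norm vector — a plane-dominated solution) or the signature is not
ellipsoidal; 0 otherwise. `aggregate_fqn()` sums the flags over a study.

## The synthetic generator

With clinical exports unavailable for redistribution, all test data are
generated. `synthetic_spec()` describes a cornea by its clinical
parameters; the ellipsoid is recovered through $c = R/(1+Q)$,
$a = R/\sqrt{1+Q}$. When the two meridians imply different $c$, a true
ellipsoid cannot carry both, so the shared axis is the geometric mean of
the two implied values, the radii $R_x, R_y$ are preserved and the
realized asphericities recomputed — the ground truth stays inside the
fitted model family by construction, so recovery tests are exact. The
out-of-family stress comes from the cone deformation: a Gaussian bump
(amplitude, width, center) emulating the localized protrusion of
keratoconus.

Defaults emulate the acquisition: 3 µm Gaussian elevation noise in the
cohort presets (5 µm in the recovery studies — the order of Scheimpflug
repeatability at the apex), dropout as sentinel substitution in three
spatial patterns (`random` scattered cells, `wedge` for a contiguous
angular sector as under an eyelid or tear-film break, `ring` for lost
peripheral coverage). Cohort presets draw per-eye parameters:
$R_x \sim \mathcal N(7.8, 0.25)$ mm, asphericity means
−0.31 / −0.62 / −0.73 / −0.85 for control / AK1 / AK2 / AK3-4 with cone
amplitudes 0 / 0.02 / 0.05 / 0.10 mm — the control values around the
healthy prolate range and the graded drift of $Q$ toward −1 with
increasing ectasia severity; asphericities are truncated to
$(-0.95, -0.05)$ to stay in the ellipsoidal regime.

What the generator does **not** emulate: ray-path-dependent (radially
correlated, heteroscedastic) Scheimpflug noise, tear-film spatial
correlation, true biconic or higher-order corneal shape families,
posterior-surface coupling to pachymetry, or instrument decentration
statistics. Passing tests therefore demonstrate correctness of the
algorithms under controlled conditions — exact-recovery identities,
noise-floor behaviour, robustness to missing data — not clinical
equivalence on patient corneas.

## Numerical choices and degenerate inputs

* Elevation solving uses the numerically stable quadratic formula; with
  two real roots the one nearer the reference elevation is returned (the
  measured value when computing MSE, the apex when sampling a synthetic
  cap — the "inner" corneal root). A double root is returned as is.
* $|a_{33}| < 10^{-14}$ (on the unit-norm vector) switches to the linear
  solve; if the linear coefficient is also below threshold the node is
  unresolved. Thresholds are meaningful because coefficients are
  normalized.
* The comparison of elevations with the sentinel is exact (`==`): −1000
  is a code, not a measurement.
* Degenerate grids (zero rows, non-increasing radii, non-finite cells),
  all-sentinel grids, clouds under 10 points, coplanar clouds and
  non-ellipsoid canonicalizations all raise typed, early errors; batch
  comparison records per-case failures instead of aborting.
* STL export samples the cap on a golden-angle sunflower lattice —
  near-uniform and free of the cocircular degeneracies a regular polar
  grid would feed the Delaunay triangulation (the triangulation is an
  in-package Bowyer–Watson; its triangle counts are cross-checked in the
  tests against the Euler bound $2n - 2 - h$). Facets are wound so
  normals face the +z hemisphere; the mesh is an open cap by design.

## Problem sizes

The test suite exercises the full 24 × 256 grid with the default
1000-individual GA in the acceptance checks (20 noiseless oracle
comparisons, 20 recovery runs at 5 µm noise, 40 dropout runs at 0–30 %),
and a 12 × 64 grid spanning the same 4.8 mm aperture with a 400-individual
GA in the unit tests — sizes chosen to keep the whole suite in the
minutes range while leaving the study conditions intact where they are
asserted. The acceptance script's cohorts (6 control + 12 keratoconus
surfaces, three methods) regenerate the comparison-table structure at the
same full grid size.

## Known limitations

* One quadric per surface: a single ellipsoid cannot represent a true
  biconic (independent meridian $c$'s) or the local cone itself; the fit
  returns the best valid ellipsoid and the deformation shows up in the
  MSE, as it should.
* On strongly cone-deformed clouds the *constrained* optimum (valid
  ellipsoid) can have a higher elevation MSE than an invalid-signature
  solution an unconstrained baseline finds; the comparison tables show
  this as lower LSQ MSE alongside nonzero LSQ FQN. Reading MSE without
  FQN inverts the methods' actual clinical usefulness.
* GA terminal precision is bounded by population fixation (see above);
  for machine-precision algebra use `fit_direct_linear()`.
* The CSV reader handles the polar dialect family, not proprietary
  binary exports; acquisition-quality scoring of repeated scans is a
  clinical step outside the package.
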