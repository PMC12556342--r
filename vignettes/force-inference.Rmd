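---
title: "Inferring membrane tensions and cell pressures from segmented epithelia"
author: "epiforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring membrane tensions and cell pressures from segmented epithelia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiforce)
```

## The model

Epithelial mechanics at the scale of a segmented microscopy image is
well captured by a network of membranes under line tension meeting at
tricellular junctions, with each cell holding a (relative) hydrostatic
pressure. `epiforce` infers both quantities non-invasively from the
segmentation alone.

**Vocabulary.** A *pivot* vertex is a junction where three or more
cells meet, or a vertex at the tissue border; every other segmentation
vertex is *virtual*. A *membrane* is the maximal chain of vertices
between two pivots, shared by two cells; it carries a single tension
unknown $\lambda$. The direction a membrane pulls on its pivot is the
unit tangent (*versor*) of a circle fitted to the membrane's chain,
evaluated at the pivot.

**Static mode.** In mechanical equilibrium the force at every pivot
$i$ vanishes:
$$\sum_{\langle ij \rangle} \lambda_{ij}\, \hat r_{ij} = 0,$$
one equation per coordinate. Collecting all equations gives a
homogeneous linear system $M_\lambda X = B$ with one column per
membrane. Because any multiple of a solution is again a solution, the
mean tension is pinned to one, $\sum_k \lambda_k = E$, implemented as
a row of ones with right-hand side $E$ and an extra uniform (Lagrange)
column, for $2V + 1$ equations in $E + 1$ unknowns over the included
pivots and membranes.

**Dynamic mode.** When junctions move, inertia is negligible at tissue
scale (low Reynolds number) and a viscous damping force proportional
to the junction velocity balances the tension imbalance:
$$\sum_{\langle ij \rangle} \lambda'_{ij}\, \hat r_{ij}
  = \rho\, \frac{\vec v_i}{\bar v},
  \qquad \rho = \frac{\eta\, \bar v}{\bar \lambda},$$
where $\bar v$ is the time-and-junction average of the junction speed
and $\rho$ — the *scale parameter* — is the dimensionless ratio of
viscous to elastic force scales. At $\rho = 0$ the dynamic system is
bitwise the static one. The per-frame tissue motility $|v|_2$ is the
2-norm of the velocity right-hand side (constraint row excluded).

**Pressures.** Given tensions, the Young–Laplace relation across each
cell–cell membrane,
$$P_2 - P_1 = \lambda\,\kappa,$$
links the pressure difference to the signed membrane curvature. One
row per membrane, one column per cell, and the gauge $\sum_c P_c = 0$
give relative pressures. Curvature is signed positive when the fitted
circle's center lies on the cell-2 side, so the concave-side cell (the
one the center sits in) has the higher pressure. Membranes against the
background contribute no rows: the exterior pressure is not inferable
without a boundary model.

## Solving the constrained systems

Both systems are solved as equality-constrained least squares,
$$\min_X \lVert M X - B \rVert^2 \quad \text{s.t.} \quad c^\top X = v,$$
through the KKT system
$\begin{pmatrix} 2M^\top M & c \\ c^\top & 0\end{pmatrix}$.
This realizes the intent of the appended constraint row while
satisfying the mean-one (tensions) and mean-zero (pressures)
normalizations *exactly*, which an appended soft row does not
guarantee on inconsistent systems. The direct solve is accepted when
the KKT matrix's condition estimate is below $10^{12}$; a singular
system falls back to a minimum-norm least-squares solve, and any
negative tension (below $-10^{-9}$) engages an active-set non-negative
least squares under the same equality constraint. Solver provenance is
recorded on every solution.

Border pivots are excluded from the force rows by default: the
external forces acting on them are unknown, and including their
unbalanced rows biases interior tensions. Membranes touching no
included pivot (typically the outer rim) then drop out of the
unknowns and are reported `NA`; the mean-one constraint applies to
the included set. Degree-4+ junctions are accepted with a logged
note — force balance at such junctions is less stable.

A caveat worth knowing: the uniform Lagrange column makes *very*
small networks (one or two junctions) underdetermined — a whole
family of tensions fits exactly. Real tissues, with
$2V + 1 \gg E + 1$, are comfortably overdetermined; the package's
tests check oracle equivalence on a determined 16-cell system.

## From image to mesh

Two readers produce identical downstream behavior:

* `readSkeleton()` takes a binary, 1-pixel-wide, 8-connected membrane
  skeleton. Pixels become vertices; redundant diagonal adjacencies are
  pruned; junction-pixel clusters (2×2 raster artifacts) are merged
  into one pivot at their centroid; enclosed black regions become
  cells and the border-touching black phase is the background.
* `readLabeledMask()` takes an integer label image and traces
  boundaries on the half-pixel corner lattice; corners where three or
  more labels meet (counting background) are pivots. Non-contiguous
  labels are flagged and reduced to their largest component.

Membrane geometry uses an algebraic (Kåsa) circle fit — closed form,
deterministic, rotation-equivariant — with a collinearity guard
(singular-value ratio below $10^{-6}$ → straight chord, zero
curvature) and a 3-point minimum below which the chord is used.
Coordinates are 0-based pixel indices, x = column, y = row (downward);
physical units enter only through the optional `pixelSize` metadata.

## Pivot tracking and velocities

`trackPivots()` matches pivots between consecutive frames by greedy
mutual nearest neighbors within a maximum displacement (default half
the median membrane length — scale-aware, preventing cross-tissue
jumps), ties broken deterministically by lowest index. A JSON
correction table can override individual links, keeping mistracked
junctions repairable without touching the segmentation. Velocities
are forward differences, backward at the final frame; a junction that
cannot be followed is assigned zero velocity in the frames concerned.
$\bar v$ is computed over all frames of the series.

## The synthetic ground-truth generator

Validation needs tissues whose tensions and pressures are *known*.
The generator implements a quasistatic vertex model with energy
$$E = \sum_c \frac{K}{2}\,(A_c - A_{0,c})^2 + \sum_e \lambda_e L_e,$$
on tissues built as Voronoi tessellations (native half-plane
clipping) of a jittered $\sqrt n \times \sqrt n$ grid. The default
conditions are: $n = 64$
cells, grid spacing $\sqrt{450}$ px, target areas
$A_0 \sim N(450, 5)$, base tensions $\lambda \sim N(1, 0.1)$, area
stiffness $K = 1$, six segments per membrane. The jitter scale
(0.15 of the grid spacing) is our choice: it produces the mild
polygonal disorder typical of real epithelia without degenerate
cells.

Membranes are subdivided into chains of virtual vertices so they can
bow under pressure differences; at equilibrium each membrane is a
circular arc with curvature $\Delta P / \lambda$ — exactly the signal
the pressure inference reads out. Ground-truth pressures are the
area-constraint multipliers $P_c = K\,(A_{0,c} - A_c)$ (equivalently
$\partial E/\partial A_0$), mean-centered.

**Relaxation.** `relaxTissue()` runs rounds of L-BFGS descent with
the analytic gradient, interleaved with two housekeeping steps:

* *Chain respacing.* The line-tension term is tangentially
  degenerate — chain vertices may sit anywhere along the membrane
  path at equal energy — so they drift and bunch, stalling descent.
  Between rounds, chains are redistributed at equal arc length along
  their current polyline (the classical vertex-averaging step); the
  new points lie on the old path, so the energy cannot increase.
* *T1 swaps.* A cell–cell wall whose pivot-to-pivot chord falls below
  5% of the mean wall length undergoes a neighbor exchange (threshold
  our choice; the protocol prescribes swaps without one).

Border pivots are pinned at their positions during relaxation. A free
boundary lets rim corners slide along the rim under tension
differences — a contact-line effect that only ends in boundary-wall
collapse, a topology change outside scope. Pinning leaves every
degree of freedom the inference uses (interior pivots, all chain
vertices) at a true equilibrium; convergence is declared when the
maximum residual force on those vertices falls below $10^{-3}$ in
tension units.

**The four conditions.** `applyCondition()` reassigns tensions:
x/y furrows add an amplitude-scaled standard-normal profile of the
z-scored membrane-center coordinate (peak at the tissue centroid, sd
two mean cell radii); the circular condition uses distance to the
centroid; the random condition draws one of five base values (1, 1.1,
1.2, 1.3, 1.5) uniformly per membrane with a Gaussian spread of 50%
of the value. The furrow profile is defined only up to scale; the
amplitudes (12 for the linear furrows, 1 for circular) were
calibrated once so that the relaxed ground-truth pressure spans land
in the 0.05–0.4 range expected of vertex-model epithelia at unit
tension scale, per condition, and are not revisited. Tensions are
floored at 0.05.

**Dynamic series.** `relaxOverdamped()` integrates the overdamped
gradient flow $\dot x = -\nabla E/\eta$ ($\eta = 1$) with explicit
Euler steps (step 0.002 time units, set by the stability bound of the
area term) and records a snapshot every 0.25 time units. Because each
frame's displacement is proportional to the unbalanced force, the
series moves in exactly the regime the dynamic mode assumes, with an
emergent scale parameter $\rho = \eta\bar v/\bar\lambda$ — nothing in
the generator sets $\rho$ directly; it follows from the condition
amplitudes and the cadence.

**What the generator does and does not emulate.** It reproduces
polygonal packing, tension-driven membrane curvature, junction
motion under overdamped dynamics, topology changes, and exact
per-membrane/per-cell ground truth. It does not emulate segmentation
error (the rasterizers draw perfect 1-px skeletons), intensity noise,
out-of-plane curvature, or active fluctuations. Passing the synthetic
suite therefore demonstrates correctness of the inference given a
faithful segmentation, not robustness to imaging artifacts.

## Scoring

`mape()` is the mean absolute percentage error (stored as a fraction,
reported as %); ground truth is mean-normalized over the compared
membranes before scoring, matching the mean-one calibration of the
inference. The composite score
$$s(M, p, r) = \frac{\alpha}{M} + \frac{\beta}{2}\,
  \frac{1 + p}{1 - p} + \frac{\gamma}{1 - r}$$
(unit weights) combines MAPE, Pearson correlation and the coefficient
of determination; it is saturated at $s = 299.5$ — the value at a 1%
error, $s(0.01, 0.99, 0.99) = 299.5$ — for reporting. Two choices are
deliberate: $r$ is computed against the identity line (not a refit),
the stricter, scale-honest reading; and the scale-parameter sweep
maximizes the *uncapped* score, since an argmax over a capped plateau
would be degenerate. `sweepScaleParameter()` scans $\rho$ from 0 to
0.5 in steps of 0.01 (the resolution at which optima are reported),
taking the per-replicate argmax of the median-over-frames score and
per-condition medians. `wasserstein1d()` (ECDF-integral earth mover's
distance) supports distribution comparisons.

## Downstream analyses

* `membraneIntensity()`: membrane shapes smoothed by a third-order
  Savitzky–Golay filter over a 5-pixel window, per-vertex intensities
  median-filtered over first chain neighbors, per-membrane means
  normalized to tissue mean one — the procedure for comparing a
  myosin reporter with inferred tensions.
* `pressureWeightedDensity()` + `findDensityMaxima()`: Gaussian KDE
  of cell positions along an axis weighted by inferred pressure
  (weights shifted by their minimum, since relative pressures are
  mean-zero; the shift is reported), with maxima located by
  finite-difference sign changes — the rosette-detection procedure.
* `fitRecoil()` + `estimateScaleParameter()`: after laser ablation of
  a membrane the pivot separation follows
  $L(t) = L_0 + 2(\lambda/\eta)\,t$ at short times; an OLS line on
  the chosen window yields $\lambda/\eta$ = slope/2, and combining it
  with a characteristic velocity gives
  $\hat\rho = \bar v/(\lambda/\eta)$, the experimental estimate of
  the scale parameter. (The alternative phrasing "slope times
  velocity" is dimensionally inconsistent with the definition of
  $\rho$ and is not used.) The default window ends at 10 s, before
  recoil saturates.

## Worked example

```{r example, eval = FALSE}
# ground truth: a 64-cell tissue with an x-furrow, relaxed to equilibrium
tis <- generateVoronoiTissue(n = 64, seed = 7)
tis <- relaxTissue(tis)
tis <- applyCondition(tis, "x_furrow")
tis <- relaxTissue(tis)

# inference from the mesh (or rasterize with exportSkeleton() and read
# back with readSkeleton() to exercise the full image pipeline)
st <- solveStresses(assembleStaticSystem(tis), mesh = tis)
pr <- solvePressures(assemblePressureSystem(tis, st))
scoreInference(tensions(st), tensions(tis))   # MAPE, Pearson, score
```

## Problem sizes and defaults

The validation suites in `runValidation()` default to 64-cell
tissues, 5 replicates per condition and 10-frame dynamic series — a
desk-scale design (25 replicates per condition give the same medians
with tighter spread, at five times the cost). The scale-parameter
grid is 0–0.5 by 0.01. Tracking uses
`dt = 1` frame; all velocities are px/frame, and $\rho$ is
dimensionless regardless.

## Known limitations

* Pressures are relative (mean zero); absolute pressures would need a
  boundary model.
* The inference assumes uniform effective viscosity and per-membrane
  constant tension; subcellular tension gradients are averaged.
* Tissues whose interior is mostly degree-4 junctions (e.g. perfect
  lattices) sit at the edge of model stability, as the balance
  equations there are degenerate.
* The dynamic mode's right-hand side is not Galilean-invariant: a
  uniform drift of the whole field changes the velocities but not the
  force matrix. Drifting tissues should be registered first.
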