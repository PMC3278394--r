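---
title: "Computing 3D myocardial mechanics from cine DENSE: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing 3D myocardial mechanics from cine DENSE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Overview

Cine DENSE (Displacement ENcoding with Stimulated Echoes) MRI stores tissue
displacement in the image phase: at every cardiac phase, the phase of the
stimulated echo in encoding direction $j$ is $\phi_j = 2\pi k_e d_j$, where
$k_e$ is the displacement-encoding frequency (cycles/mm) and $d_j$ the
displacement (mm) of the tissue currently occupying the voxel, relative to
its position at the encoding moment. `denseMechanics` implements the full
processing chain from phase-cycled raw images to myocardial strain, twist,
and torsion for three-dimensional multiphase acquisitions, together with an
analytic deforming left-ventricle phantom that supplies exact ground truth
for every stage.

The chain is:

1. **Reconstruction** — per-voxel least-squares combination of the three
   phase-cycled acquisitions isolates the stimulated echo
   (`combinePhaseCycles()`); background phase is removed wrap-safely by
   complex conjugate multiplication (`subtractBackground()`); the combined
   magnitude is the root sum of squares over encoding directions
   (`magnitudeRSS()`).
2. **Segmentation** — endo/epicardial contours drawn at the first cardiac
   phase are propagated to all phases with the measured displacement
   (`propagateContours()`) and rasterized partition-by-partition into
   myocardial masks (`rasterizeMask()`).
3. **Phase unwrapping** — a quality-guided floodfill extended to three
   spatial dimensions plus time (`unwrapSpatiotemporal()`); unwrapped phase
   divides by $2\pi k_e$ to give Eulerian displacement
   (`phaseToDisplacement()`, `assembleVectorField()`).
4. **Tissue tracking** — Eulerian displacements are converted to Lagrangian
   trajectories of the voxel centers identified at the first phase through
   scattered-data interpolation with linear-spline radial basis functions
   (`buildTrajectories()`), then lightly smoothed with 10th-order
   polynomial fits (`smoothTrajectories()`).
5. **Mechanics** — for every material voxel, the deformation gradient is
   solved from the trajectories of its $N \le 12$ nearest neighbors via the
   SVD pseudo-inverse, the Lagrangian finite strain tensor
   $E = (F^\top F - I)/2$ is formed and projected onto the local
   radial/circumferential/longitudinal (RCL) frame (`computeStrain()`), and
   slice twist plus normalized torsion
   $(\theta_{apex}-\theta_{base})\,R_{LV}/L_{LV}$ are computed
   (`computeTwistTorsion()`).

`runPipeline()` orchestrates all stages deterministically given a seed.

# The strain estimator

For a voxel of interest with reference position $u_0$ and neighbor
positions $p_{0,i}$, the columns of $V_0$ are the reference distance
vectors $q_{0,i} = p_{0,i} - u_0$, and $V_f$ their deformed counterparts at
phase $f$. Under the local uniform-strain assumption $V_f = F_f V_0$. With
the SVD $V_0 V_0^\top = U S V^\top$, the solve is
$F_f = V_f V_0^\top V S^0 U^\top$, where $S^0$ holds reciprocal singular
values. Two numerical decisions matter here:

* **Small-singular-value rule.** Inverting every singular value is unstable
  for near-coplanar stencils (e.g. a voxel whose neighbors all lie in one
  partition). Singular values below $10^{-6}$ of the largest are zeroed in
  $S^0$ (pseudo-inverse convention), which reproduces ordinary least
  squares on full-rank stencils — the test suite verifies equality with a
  brute-force normal-equations solve to $10^{-8}$ — and degrades gracefully
  on rank-2 stencils (the in-plane block is still recovered exactly).
* **Neighbor stencil.** Up to 12 nearest neighbors by reference distance,
  restricted to the voxel's own partition and the two adjacent ones, with
  deterministic tie-breaking in (partition, row, column) order. Voxels with
  fewer than 3 valid neighbors, rank-deficient geometry, or an undefined
  radial direction are flagged and excluded rather than filled.

Because $E$ depends on $F$ only through $F^\top F$, the estimator is
objective: superposing any rigid rotation plus translation on all
trajectories leaves the full tensor unchanged (verified to $10^{-8}$).

The RCL frame is anchored at the first cardiac phase: $\hat{l} = +z$ (the
grid z axis is the LV long axis, apex at low z, base at high z), $\hat{r}$
points in-plane from the slice midwall centroid to the voxel, and
$\hat{c} = \hat{l} \times \hat{r}$.

# Twist and torsion conventions

Twist is the signed in-plane angle between the centroid-to-voxel radial
lines at the first phase and at phase $f$; positive twist is clockwise
viewed from the base. Three estimator choices are not fixed by the method
description and are resolved as follows:

* **Slice center**: the per-phase myocardial centroid of the slice, so bulk
  in-plane translation does not masquerade as twist (a fixed center would
  alias translation into rotation).
* **$\theta_{apex}, \theta_{base}$**: circular-mean twist over the apical
  and basal thirds of the analyzed partitions (single extreme slices are
  noisier; ranges match how level summaries are formed).
* **Normalization**: $R_{LV}$ is the mean midwall radius of the phase-1
  contours over analyzed slices; $L_{LV}$ is the axial distance between the
  basal and apical range centers. The ratio makes torsion independent of
  ventricle size.

Voxels lying at the slice centroid have no defined angle and are dropped
from the circular mean. End systole is defined globally as the phase
maximizing the mean absolute circumferential strain.

# Phase unwrapping

The quality map is the negative local variance of wrap-safe phase
differences (forward and backward, all three axes) over a 3×3×3
neighborhood: smooth phase scores near zero, noise and residual wraps score
strongly negative. Unwrapping proceeds per phase: a priority-queue
floodfill (6-connectivity, implemented in C++) grows from the
maximum-quality voxel, each popped voxel taking its integer wrap count from
its best already-unwrapped neighbor, so the output is congruent to the
input modulo $2\pi$ *by construction* (integer wrap counts are tracked, not
floating-point sums). Temporal guidance predicts each phase from the
previous unwrapped phase and floodfills only the wrapped residual; the
first phase, which carries the smallest true motion, is anchored by
choosing the integer global offset that minimizes its mean phase.
Disconnected mask components are unwrapped independently, each receiving
its own integer offset the same way. Voxels whose displacement magnitude
exceeds a physiologic cap (default 3 mm — half the phantom ventricle
length; mouse LV displacements stay well below this) are flagged
unreliable, never deleted.

# Tissue tracking

A voxel at deformed position $x$ at phase $f$ holds tissue that was at
$x - d(x, f)$ at encoding, so the scattered samples
$(x_i - d_i) \mapsto x_i$ define the reference-to-deformed map. The
interpolant uses $\varphi(r) = r$ kernels plus an affine polynomial term
with the standard side conditions, which reproduces affine motions —
translations, rotations, uniform scalings — exactly; the tests require
better than 0.01 voxel on such fields. Two numerical choices:

* a diagonal regularization of $10^{-8}$ times the mean inter-point
  distance keeps the saddle system well-conditioned;
* when a phase offers more scattered samples than `maxCenters` (default
  2000), sites are subsampled deterministically with a regular stride in
  lexicographic (z, y, x) order. One global solve per phase with spatially
  spread centers is preferred over per-query local solves: the linear
  kernel is local enough that accuracy is unaffected at these densities,
  and the cost drops from thousands of medium systems to one factorization
  per phase.

Trajectory smoothing fits each coordinate with an order-10 polynomial over
time normalized to $[0,1]$ (order reduced to `nPhases - 2` for short
series). The fit is an unconstrained least-squares projection — it is not
forced through the phase-1 point — hence linear and idempotent.

# The phantom

The synthetic data generator is a first-class, tested module, not a
fixture. It models the left ventricle as an axisymmetric thick-walled
annulus (reference endo/epi radii 1.5/2.5 mm, length 6 mm — a murine LV
with average radius 2 mm) undergoing three superposed motions with a
raised-cosine time course peaking at the systolic phase index:

* **In-plane contraction.** The endocardial radius scales by
  `peakContraction`; with `incompressible = TRUE` the radial profile solves
  $r^2 = r_{endo}^2 + (R^2 - R_{endo}^2)/\lambda_l$, which preserves
  cross-sectional area between the walls relative to the axial stretch so
  that $\det F = 1$ exactly, everywhere, at every phase (tested by finite
  differences to $10^{-6}$). With `incompressible = FALSE` the in-plane map
  is a uniform scale — useful for closed-form checks such as
  $E_{rr} = E_{cc} = (\lambda^2-1)/2$.
* **Twist**, a rotation about the long axis linear in the axial
  coordinate, apical tissue rotating clockwise viewed from the base.
* **Longitudinal shortening**, affine about the apex.

Because the map is closed-form and invertible, the renderer evaluates it
*Eulerian-wise*: each voxel's phase encodes the exact displacement of the
tissue occupying it, wrapped into $(-\pi, \pi]$, with complex Gaussian
noise added to the per-direction complex signal before phase extraction
(SNR defined linearly on the annulus magnitude). The analytic deformation
gradient in the cylindrical frame,

$$F = \mathrm{diag}\!\left(\frac{dr}{dR},\ \frac{r}{R},\ \lambda_l\right)
      + r\,\alpha'(Z)\; \hat{e}_\theta \otimes \hat{e}_Z,$$

yields exact RCL strains ($E_{rc} = E_{rl} = 0$, $E_{cl}$ from the twist
gradient), exported per reference voxel per phase together with the exact
Eulerian displacement, per-phase Eulerian masks, contours, and analytic
twist.

Default motion amplitudes (contraction 0.72, shortening 0.12, twist
1.4°/mm, systole at phase 6 of 14) were chosen once to land midwall peak
strains and apical twist in the physiologic range reported for healthy
mice (midwall $E_{cc} \approx -0.11$, $E_{rr} \approx 0.32$,
$E_{ll} \approx -0.11$, apical twist ≈ 8°). Acquisition defaults follow the
small-animal protocol: $k_e = 1.1$ cycles/mm, 14 cardiac phases,
0.25 × 0.25 × 0.4 mm voxels, SNR 20. The default field of view is
8 × 8 × 8.8 mm (a 32 × 32 × 22 grid — the protocol's partition count with a
desk-scale in-plane extent that still covers the whole phantom ventricle
with margin). The phase-cycling simulator uses increments
$\{0, 2\pi/3, 4\pi/3\}$ and a phase-cycle-invariant artifact echo (a smooth
complex field); the invariance is a modeling choice — real artifact echoes
may retain partial phase-cycle dependence — and is exactly the structure
the least-squares combination assumes, which is what makes the noiseless
combination test an algebraic identity rather than an approximation.

What the phantom does *not* emulate: through-plane signal loss, T1
recovery and flip-angle modulation of the stimulated echo, off-resonance
blurring, spiral k-space artifacts, papillary muscles, regional wall-motion
heterogeneity, or a closed apex. Passing the phantom suite therefore
demonstrates the correctness of the computational chain — encoding
inversion, unwrapping, tracking, tensor algebra, conventions and signs —
not robustness to every in-vivo confounder.

# Background phase

The method subtracts background phase but does not characterize its source
or operand; the package accepts either an explicit complex reference image
or a stored background field (`reconSeries(reference = )`), and the phantom
can optionally superpose a low-order polynomial background field (default
off) to exercise the wrap-safe subtraction.

# Pipeline bootstrapping

Contour propagation needs displacement, and unwrapping needs per-phase
masks — a genuine chicken-and-egg. `runPipeline()` resolves it in two
passes: the phase-1 mask is dilated by the expected per-phase motion
(default 2 voxels in-plane, 1 partition axially) and intersected with a
stimulated-echo signal mask (magnitude above half the median myocardial
magnitude — the dilation ring outside the myocardium carries no stimulated
echo, only noise whose phase would poison the scattered-data fit);
unwrapping and a provisional displacement field are computed there; the
phase-1 contours are then propagated materially, rasterized into final
per-phase masks, and the displacement field is restricted to them before
tracking and strain estimation.

Propagated contours are stored with the mean mapped axial position of
their vertices; rasterization assigns each image partition the contour
nearest its plane (within half a partition thickness), so longitudinal
shortening correctly empties basal partitions the tissue has left.

# A note on the incompressibility check

For an isochoric deformation, $\operatorname{tr} E = 0$ holds only to
first order in strain: with
$2E_{ii} = \lambda_i^2 - 1$ and $\prod \lambda_i = 1$, the exact trace at
the default phantom's physiologic strain magnitudes is ≈ +0.10, not zero.
The trace-based validation is therefore run on a gently contracting
incompressible phantom (contraction 0.95, shortening 0.05, twist 0.5°/mm)
where the small-strain statement applies; the default phantom's
incompressibility is verified exactly, via $\det F = 1$, at the motion
model itself.

# Problem sizes and determinism

The validation suite runs the phantom at two scales: a coarse grid
(0.5 × 0.5 × 0.8 mm voxels, 6 phases, ≈ 800 myocardial voxels per phase)
for per-module checks, and the full default study (32 × 32 × 22 grid, 14
phases, ≈ 3200 myocardial voxels per phase) for the end-to-end recovery
check, which completes in well under a minute. All stochastic stages
derive from a single integer seed; identical seeds give byte-identical
series, tables, and provenance-stamped outputs (every written table
carries the MD5 hash of the generating config).

# Known limitations

* Segmentation is 2D partition-by-partition, mirroring the method; no 3D
  endo/epicardial surface model, and no automatic initial delineation.
* The unwrapper assumes true per-voxel phase steps below $\pi$ within the
  myocardium; pathological inter-voxel motion would need branch-cut or
  minimum-norm methods that are deliberately out of scope.
* Temporal smoothing is polynomial only; no splines or Fourier bases.
* The in-vivo strain and torsion values reported for real mice are
  measurement distributions across animals; the phantom reproduces their
  range, not their biological variability.
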