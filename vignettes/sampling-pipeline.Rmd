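---
title: "Cardiac source sampling and the ECG forward solution: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac source sampling and the ECG forward solution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgfwd)
```

## The problem

Electrocardiographic imaging and its validation rest on the *forward
problem*: given electric potentials on a closed surface surrounding the
heart (the pericardial surface), predict the potentials on the body
surface through the passive, quasi-static volume conductor of the torso.
Experimental validation studies usually record cardiac potentials with a
sock electrode array pulled over the ventricles. The sock leaves the atria
— and often the ventricular base — unsampled, yet the mathematics of the
potential-based forward formulation assumes a *complete* closed source
surface. This package quantifies the error that incomplete sampling
injects into the forward solution, and compares strategies for spending a
limited budget of additional atrial electrodes.

Because the original experimental and simulated datasets live in external
databases, the package generates synthetic scenes with the same structure:
a closed cardiac surface of roughly 500 nodes (ellipsoidal "sock plus cap"
or cylindrical "cage" preset) inside an ellipsoidal torso of roughly 770
nodes and ~360 × 220 × 400 mm, with ventricular/atrial regions split by an
atrioventricular (AV) plane so that about a quarter of source nodes are
atrial.

## Pipeline

For a scene, source potential frames $\Phi(t)$ and a sampling plan, the
experiment is:

1. **Ground truth**: body-surface potentials $\Phi_{gt}(t) = T\,\Phi(t)$
   at *full* source sampling, where $T$ is the BEM transfer matrix.
2. For each iteration of the plan: restrict $\Phi$ to the measured nodes,
   reconstruct the unmeasured nodes by Laplacian interpolation, forward
   solve, and score against $\Phi_{gt}$ with the three standard metrics.

Ground truth deliberately comes from the *same* BEM operator, not an
independent volume solver: full-sampling error is then identically zero
and every curve reads as pure sampling-induced error. The corresponding
solver-family discrepancy that a FEM reference would add is intentionally
excluded; consequently nothing in this package estimates the absolute
accuracy of BEM itself beyond the analytic oracle below.

## The forward operator

The torso interior is a homogeneous, source-free conductor bounded by the
cardiac surface (Dirichlet data $\Phi_H$) and the insulated torso surface
($\partial\Phi/\partial n = 0$). Green's representation collocated at the
vertices of both surfaces gives, with $W$ the double-layer (solid-angle)
blocks, $S$ the single-layer blocks and $g_H$ the unknown normal gradient
on the source surface:

$$4\pi c_i \Phi_i \;=\; W^{iT}\Phi_T \;-\; W^{iH}\Phi_H \;-\; S^{iH} g_H .$$

Design choices that matter numerically:

* **Linear shape functions, analytic integrals.** On each plane triangle
  both kernels are integrated in closed form. Writing the linear shape
  function about the in-plane projection $q$ of the field point,
  $N_k(r') = N_k(q) + g_k\!\cdot\!(r'-q)$, the shape-weighted solid angle
  reduces to $N_k(q)\,\Omega - d \sum_e (g_k\!\cdot\!\hat m_e) f_e$ with
  $\Omega$ the van Oosterom–Strackee solid angle, $d$ the signed distance
  to the triangle plane, and $f_e$ per-edge logarithms; the single layer
  reduces to the classical edge-wise closed form of the constant and
  linear moments. No quadrature rule, hence no quadrature tolerance, is
  involved anywhere in assembly. Degenerate configurations (field point in
  the triangle plane, or collinear with an edge) are principal values
  handled by explicit guards, verified during development against dense
  numerical quadrature to ~1e-8.
* **Auto solid angle.** The $4\pi c_i$ diagonal is never computed
  geometrically; it is recovered from the row sums of the double-layer
  blocks under a constant field. This makes $T\mathbf{1} = \mathbf{1}$
  hold to machine precision, which the constant-reproduction test checks
  end to end.
* **No deflation by default.** The insulated-torso double-layer block
  alone is singular (constants), but after eliminating $g_H$ through the
  single-layer block the system is uniquely solvable and well conditioned;
  deflating unconditionally would perturb the solution. A rank-one
  deflation plus zero-mean re-referencing remains available via
  `assemble_transfer(scene, deflate = TRUE)` for hostile geometries.
* **Dense storage and direct solves** (problem sizes are a few thousand
  nodes at most).

**Oracle.** On concentric spheres (inner $R_1$ Dirichlet, outer $R_2$
insulated) the solution for boundary data $Y_{lm}$ is
$(A r^l + B r^{-(l+1)}) Y_{lm}$ with $A, B$ from the two boundary
conditions (`shell_solution()`). The acceptance suite requires relative
L2 error $\le 2\%$ at source subdivision 3 / torso subdivision 4 for
$l \in \{1,2,3\}$ (measured: 0.2–1.2%) and monotone convergence as both
spheres are refined through subdivisions 2, 3, 4. Refining only the torso
to subdivision 5 would create a 10k-node dense system beyond the stated
runtime budget, so the convergence sweep refines the pair jointly.

## Laplacian interpolation

Unmeasured source potentials are reconstructed by making the interpolant
discretely harmonic: with the surface Laplacian $L$ partitioned into
known/unknown blocks, solve $L_{uu}\Phi_u = -L_{uk}\Phi_k$ by direct
sparse factorisation (relative residuals ~1e-10; iterative solvers are
not used, for determinism). Two weight schemes are provided because the
discretisation behind the method's standard citation is distance-based
while modern surface-PDE practice is cotangent-based:

* `cotangent` (default): linear precision on planar meshes — a linear
  field sampled on a patch boundary is recovered at interior vertices to
  1e-9;
* `inverse_distance`: strictly positive weights, hence a guaranteed
  discrete maximum principle (interpolated values never leave the range of
  the measured values), checked on 100 random sampling masks.

Equivalence with any particular legacy implementation's stencil is *not*
claimed. Known values pass through untouched, so a fully measured frame is
returned identically.

## Synthetic sources

Ventricular activation is emulated by 2–3 current dipoles inside the
heart, swept from apex toward base over the frame window with moments
rotating 90°, evaluated with the infinite-medium dipole formula
$\Phi = p\cdot(r - r_0)/(4\pi\sigma|r-r_0|^3)$. Defaults and rationale:

* `n_frames = 20`, 1 ms per frame: a short ventricular-activation window.
* Peak magnitude 30 mV: epicardial-order realism. The source magnitude is
  a presentation choice only — every reported metric is either a ratio or
  scales linearly with it — and it is never asserted against external
  numbers.
* Conductivity 0.2 S/m, homogeneous: cancels in all metrics; carried for
  dimensional bookkeeping.
* Atrial activation is *not* simulated (matching the stated assumption of
  the study design this pipeline follows); atrial-surface potentials are
  the passive far field of ventricular dipoles.

The generator is a pure function of `(scene, n_frames, seed)`, and each
stored value equals the declared dipole sum exactly, which the tests
re-evaluate per vertex. What the synthetic world does **not** contain:
propagating wavefronts with realistic spatial frequency content,
endocardial sources, measurement noise, electrode registration error, or
torso inhomogeneities. A green directional test therefore establishes that
the *pipeline* reproduces the qualitative sampling findings in a clean
world, not that those findings transfer quantitatively to any animal or
patient dataset.

## Sampling strategies

All additive plans fix the ventricles as measured and add atrial nodes in
`n_iterations` near-equal bands (sizes differ by at most one; default 7
iterations, configurable to match other mesh densities): `av_first` and
`roof_first` order atrial nodes along the long axis (the latter is the
exact reverse of the former, which keeps the two plans band-for-band dual
when the counts divide evenly — an independent descending sort would break
that duality on meshes where rings of nodes share an axial level);
`combined` alternates ends of the same ordering; `uniform` is
farthest-point sampling seeded at the node nearest the atrial centroid
(the standard deterministic realisation of "uniformly distributed");
`random` is a seeded permutation. `plaque_cluster()` picks the $k$ nearest
atrial nodes to a centre; `plan_basal_removal()` peels ventricular bands
base-first down to a default 45% removal, emulating the loss of basal sock
contact. Ties everywhere break by lowest vertex index.

## Error metrics

Per frame, against ground truth $\Phi_{gt}$: RMS error
$\bar E = \lVert\Phi_{gt}-\Phi_s\rVert/\sqrt n$ (the literal
$/n$ convention used by some reports is selectable and every summary
names its convention); relative RMS error
$\lVert\Phi_{gt}-\Phi_s\rVert/\lVert\Phi_{gt}\rVert$; and the
**uncentered** cosine correlation
$\Phi_{gt}^{\mathsf T}\Phi_s/(\lVert\Phi_{gt}\rVert\lVert\Phi_s\rVert)$ —
deliberately not Pearson correlation, with a centred variant available
for sensitivity checks only. Frames whose ground-truth norm is below
1e-9 of the window maximum are reported as excluded rather than silently
skipped, because the relative metrics are undefined there. Summaries are
the mean and the worst case (max for errors, min for correlation) over an
explicit frame window (default: all frames, since the synthetic window
models ventricular activation only).

## What the default experiment shows

On the default scene averaged over five seeds: every strategy's
ventricle-only baseline error exceeds its full-sampling error (which is
exactly zero by construction); the distributed strategies (uniform,
random) reach low error with far fewer added electrodes than the
single-direction strategies, with a seed-averaged area-under-curve ratio
of roughly 0.4; every atrial plaque placement improves on the
ventricle-only baseline; and maximal basal removal degrades the mean
correlation. These are recomputed — never hard-coded — by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`. Because
full-sampling error is exactly zero, the "electrodes to reach 1.1× the
full-sampling error" column of `compare_strategies()` saturates at the
full electrode count by construction; the area under the error curve is
the informative ranking statistic in this package.

## Numerical edge cases and limitations

* Meshes are validated for manifoldness, consistent orientation and
  positive triangle areas; open meshes are legal everywhere except BEM
  assembly, which requires closed surfaces and verifies containment
  through total solid angles.
* The ellipsoidal cap fits the quadric to the boundary loop *plus two
  rings of adjacent interior vertices*: a single near-planar ring does not
  determine an ellipsoid.
* Cotangent weights may be negative on obtuse triangles; only the
  inverse-distance scheme guarantees the maximum principle. Degenerate
  triangles fall back to inverse-distance weights and are counted.
* The `uniform` plan records its seed argument for interface symmetry but
  is fully deterministic.
* No inverse (imaging) solver, no torso inhomogeneities, no endocardial
  surface, and no ingestion of external database formats are provided.
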