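---
title: "Mechanical resonance modes of multi-compartment brain phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanical resonance modes of multi-compartment brain phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Correlated large-scale patterns of brain activity can be described as
superpositions of standing waves — eigenmodes — of the brain. Most
eigenmode work derives these modes from cortical geometry or connectivity
alone. This package treats the head as an elastic continuum instead: a
heterogeneous solid of white matter (WM), gray matter (GM), cerebrospinal
fluid (CSF, modeled as a soft nearly incompressible elastic solid) and
skull, so that the *material properties* of the tissues, not only the
geometry, shape the modes.

Undamped free vibration of the discretized solid is governed by

$$[M]\{\ddot u\} + [K]\{u\} = 0,$$

and harmonic motion $\{u\} = \{\phi\}_i \sin(\omega_i t + \theta_i)$
reduces it to the generalized eigenproblem

$$([K] - \omega_i^2 [M])\{\phi\}_i = 0,$$

whose eigenvalues $\omega_i^2$ give the natural frequencies
$f_i = \omega_i / 2\pi$ and whose eigenvectors $\{\phi\}_i$ are the mode
shapes. The package assembles $[K]$ and $[M]$ for heterogeneous isotropic
linear elasticity on 4-node (constant-strain, C3D4-type) tetrahedra,
applies Dirichlet constraints by elimination, and extracts the lowest 25
modes — the large-scale, physiologically interpretable deformations — with
a shift-invert Lanczos solver.

Two standard structural-dynamics metrics compare modal results. The Modal
Assurance Criterion between shapes $\varphi_A$, $\varphi_B$,

$$\mathrm{MAC} = \frac{(\varphi_A^T \varphi_B)^2}
                      {(\varphi_A^T\varphi_A)(\varphi_B^T\varphi_B)},$$

is 1 for identical shapes (up to scale and sign) and 0 for orthogonal
ones; modes of two models are paired by the one-to-one assignment
maximizing total MAC (Hungarian algorithm), and paired frequencies are
compared with the Normalized Relative Frequency Difference
$\mathrm{NRFD} = |f_r - f_v| / f_r$, with the reference model in the
denominator.

## Units

All computations use the mm / ton / s system: lengths in mm, Young's
moduli in MPa (N/mm²), densities in ton/mm³. In this system
$\omega^2$ from the eigenproblem is in s⁻² and $f = \omega/2\pi$ is in Hz
with no conversion factor — brain densities around $10^{-9}$ ton/mm³ and
moduli of a few hundredths of an MPa give fundamentals of tens of Hz at
head scale.

## The synthetic phantom

Anatomical meshes (template-derived, millions of elements) are cluster
scale; the package's `build_layered_phantom()` replaces them with nested
quasi-ellipsoidal shells — WM core, GM shell, CSF layer, 5 mm skull
shell — that preserve the topological layering which drives the
heterogeneity findings: soft brain tissue inside a stiffer CSF layer
inside a rigid skull. The mesh is built from subdivided-icosahedron
surfaces connected radially by prisms, each split into three tetrahedra
with the min-vertex-diagonal rule, so construction is deterministic,
conforming, and needs no external mesher. Defaults: outer shell radii
60/70/75/80 mm, axes scaled by (1, 0.85, 0.8) for a mildly ellipsoidal
head, and a seeded 0.1% node jitter. The ellipsoidal axes and jitter also
split the eigenvalue degeneracies a perfect sphere would have, which
keeps mode ordering and MAC pairing stable.

Boundary-condition node sets mirror the five fixation scenarios studied:

* `base` — outer-surface nodes within a configurable cap (default 12% of
  the z-extent) of the lowest skull point (skull-base fixation);
* neck and spine — compact cylinders (120 mm and 500 mm, skull material)
  extruded conformally from the skull's inferior surface patch, fixed at
  their far end (`cylinder_base`);
* `base_back_sides` — bottom z-quantile plus back (−y) and side (large
  |x|) sectors, emulating the cushions holding the head during an fMRI
  exam. The exact extent of such a contact patch is not standardized, so
  the quantile and sectors are configuration knobs;
* `exterior` — the brain+CSF outer surface after `strip_skull()`, for the
  no-skull scenario in which the entire exposed brain surface is fixed.

GM outer-surface nodes carry parcel labels (default 16 equal-solid-angle
sectors) so mode shapes can be projected to region vectors. A real
cortical parcellation cannot be reproduced on a phantom; the sectors only
provide a consistent region basis for quantitative comparison.

The CSF is meshed as a solid layer of prescribed thickness. Anatomically
the CSF occupies thin, irregular gaps; a phantom cannot reproduce that
thinness, so the layer thickness is part of the configuration
(`shell_radii`).

## Materials

`material_presets()` ships the parameter combinations used throughout:
brain moduli from 0.001389 to 0.497 MPa, CSF moduli on the literature
grid 2.19 / 1.314 / 0.299 / 0.1485 / 0.012 / 0.001 MPa, skull at
6000–8000 MPa, densities 1.0–1.14 × 10⁻⁹ ton/mm³ (brain/CSF) and
3.5–4.79 × 10⁻⁹ ton/mm³ (skull). The same sets are shipped as JSON under
`inst/extdata/materials/` with the literature Poisson's ratios verbatim.

Two deliberate numerical choices:

* **Poisson's ratio cap.** Literature CSF values reach ν = 0.4999. Plain
  displacement-based linear tetrahedra lock volumetrically as ν → 0.5,
  biasing frequencies upward. `material_set()` therefore caps ν at 0.49
  by default; `nu_cap = NULL` restores the literature values verbatim for
  users who want the faithful (locking-prone) configuration. The cap
  changes absolute frequencies, not the trend or invariance structure the
  experiments assert.
* **Consistent mass.** The element mass matrix is the consistent one
  (same shape functions as stiffness), the conservative default for
  eigenfrequency accuracy on linear tetrahedra; `assemble(...,
  mass = "lumped")` provides the row-sum lumped alternative for
  comparison. Which formulation a given commercial solver uses is rarely
  reported, which is one reason absolute frequency values are not an
  acceptance surface here.

## Solver choices

The generalized eigenproblem is solved by Lanczos iteration in the
M-inner product on the shift-inverted operator $(K - \sigma M)^{-1} M$,
with full reorthogonalization, residual-checked locking and random
restarts (seeded, so results are deterministic up to eigenvector sign;
normalization then pins the largest entry of each shape to +1).
Constrained systems use $\sigma = 0$; free-free systems use
$\sigma = -10\ \mathrm{s}^{-2}$ so the semidefinite $K$ factorizes and
the six rigid-body modes emerge as numerically zero frequencies.
Acceptance of a Ritz pair requires
$\|K\phi - \omega^2 M\phi\| \le 10^{-6} \max(\|K\phi\|,\ \bar\lambda \|M\phi\|)$
where $\bar\lambda$ is a fixed spectral scale of the pencil — the second
term keeps the test meaningful for rigid-body modes whose $\|K\phi\|$
vanishes. Repeated eigenvalues (the rigid-body sextet, near-symmetric
phantoms) are handled by locking-and-restart deflation rather than by a
block method. A dense full-spectrum route (`solve_modes_dense()`, Cholesky
reduction plus `eigen()`) serves as an independent oracle on small
systems; the two routes agree to 10⁻⁸ in the test suite.

## What the experiments assert

Phantom meshes are 10³–10⁴ elements, three orders of magnitude below
anatomical production meshes, so absolute frequencies are mesh-specific
and are never asserted against published values. The experiment drivers
instead check what survives any resolution:

* **Exact global-scaling law** (`run_ratio_hypothesis()`): scaling every
  region's E by one factor c scales K exactly by c, so every frequency
  scales by √c and every shape is unchanged (MAC = 1). This is the sharp
  form of the observation that mode shapes follow the brain-to-CSF
  stiffness *ratio* while frequencies follow the absolute moduli. The
  approximate-ratio pairs (higher-stiffness brain with 1 kPa CSF vs
  lower-stiffness brain with 0.1 kPa CSF, and the 12 kPa vs 1 kPa CSF
  pairing) are reported as MAC distributions, not asserted.
* **Monotonicity** (`run_csf_sweep()`): raising any region's E adds a
  positive semi-definite increment to K, so by Courant–Fischer no
  eigenfrequency decreases; along the decreasing CSF grid every sorted
  frequency is non-increasing and the fundamental's NRFD against the
  2.19 MPa reference is non-decreasing. The sweep also reports the rank
  correlation between pair MAC and mode frequency, which comes out
  negative — higher-frequency shapes are more sensitive to the CSF
  modulus.
* **Boundary-distance trend** (`run_bc_comparison()`): the fundamental
  frequency drops as the fixed boundary moves away from the brain
  (skull base → neck base → spine base), and the no-skull and fMRI-style
  scenarios are compared pairwise on shared brain nodes. Distinct mode
  shapes across the five scenarios are counted with a greedy MAC-library
  at the configurable pairing threshold (0.5 by default; no canonical
  value exists, so the count is reported together with the threshold).
* **Complexity comparison** (`run_complexity_comparison()`): the
  heterogeneous and homogeneous models share one mesh, making the MAC
  well defined; pairing bookkeeping (paired + unique = 25) and, when the
  heterogeneous stiffness dominates region-wise, the frequency ordering
  are asserted.

Cross-mesh mode comparison in general (different phantoms, or phantom vs
image-derived modes) is out of scope: the MAC needs a shared DOF basis,
and scenarios here are compared on the shared nodes of one phantom
family.

## Synthetic BOLD signals and empirical modes

The LEiDA-style pipeline — instantaneous phase by the FFT analytic
signal, per-timepoint phase-alignment matrix
$A_{ij} = \cos(\theta_i - \theta_j)$, leading eigenvector, k-means into
K = 8 recurring modes — operates on synthetic signals from
`simulate_bold()`. The generator plants a global in-phase state plus
anti-phase block states on a narrowband carrier (0.05 cycles/sample) with
additive Gaussian noise, and records the ground truth. Anti-phase blocks
are kept strictly smaller than half the regions: a block of exactly half
would make a state indistinguishable from its complement (their
phase-alignment matrices are identical), a degeneracy of the physics, not
of the estimator. The sign convention (majority of components negative)
matches published LEiDA outputs, and all matching uses absolute cosine
similarity, so results do not depend on the convention.

What the generator does *not* emulate: hemodynamics, scanner noise
spectra, preprocessing artifacts, anatomical parcellations, or
inter-subject variability. Passing recovery tests (mean matched |cosine|
≥ 0.9 over 10 seeds at 16 regions × 2000 timepoints, noise SD 0.2) shows
the estimator recovers planted phase-locking structure — not that real
resting-state data contain such structure. The quantitative
eigenmode-to-empirical-mode matching (`project_mode_to_parcels()` +
`match_eigenmodes_to_empirical()`) is likewise a package extension: it
makes a visual comparison reproducible on phantoms, and no published
number depends on it. The frequency scales of the two sides (tens of Hz
for elastic modes, ~1 Hz and below for hemodynamic patterns) are reported
side by side and deliberately not reconciled.

## Problem sizes and determinism

Default test and example sizes: four-shell phantoms at 16–18 mm edge
length (4–8 × 10³ elements, ~10⁴ DOFs), bars up to ~7 × 10³ elements,
signals 16 × 2000. A full five-scenario comparison at these sizes runs in
minutes on one core; halving the edge length roughly octuples element
count. Everything is deterministic given a configuration: phantom
construction from `phantom_config(seed=)`, eigensolver start vectors from
`solve_modes(seed=)`, signal generation and clustering from their seeds,
and `run_all_experiments()` records a config hash in its manifest so
reports regenerate identically.

## Known limitations

* Linear elasticity only: no viscoelasticity, damping, large strain, or
  fluid–structure interaction for the CSF; these change absolute
  frequencies and would add mode damping, and are out of scope.
* C3D4 elements lock near ν = 0.5 (mitigated by the ν cap, at the cost
  of fidelity to the quoted literature values).
* The phantom is topologically, not anatomically, faithful: no
  gyrification, ventricles, or realistic CSF thinness.
* Absolute eigenfrequencies depend on mesh resolution and mass
  formulation; only trends, exact laws and printed-value arithmetic are
  asserted.
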