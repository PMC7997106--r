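---
title: "Shape and electrostatic Zernike descriptors of protein surface patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape and electrostatic Zernike descriptors of protein surface patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zernpatch)
```

## The model

A protein surface patch — the solvent-accessible surface generated by a
declared set of residues — is summarized by three rotation- and
translation-invariant vectors: one for the geometry of the surface and one
each for the positive and negative parts of its electrostatic potential.
Because the description is invariant, patches can be compared across
conformations, chains and proteins without superposition, and a patch's
time evolution along a trajectory reduces to a distance series between
vectors.

The construction has four stages.

**1. Surface.** Every atom contributes quasi-uniform samples (a
deterministic Fibonacci lattice, `samples_per_atom` points) on its sphere
of radius (atomic radius + probe radius); samples falling strictly inside
any other atom's expanded sphere are discarded. This is a point-sampled
solvent-accessible surface: the locus traced by the probe center. When a
patch sits inside a larger structure, sampling is done on the full
structure and only patch-owned points are kept, so the surrounding protein
occludes correctly. The probe radius defaults to 1.4 Å (a water-sized
probe).

**2. Potential.** A bare Coulomb sum over all atomic partial charges with
a uniform relative dielectric (default 4, a conventional protein screening
value): φ(p) = (1/ε) Σᵢ qᵢ / |p − xᵢ|, charges in e, distances in Å.
Charges come from PQR input (e.g. PDB2PQR output); PDB input has none, and
its electrostatic channels are identically zero. The potential is split by
sign, φ⁺ = max(φ, 0) and φ⁻ = max(−φ, 0), because the descriptor below
retains only coefficient magnitudes: a single signed field would make +
and − patterns indistinguishable. The split is exact (φ⁺ − φ⁻ = φ,
φ⁺·φ⁻ = 0) and charge negation swaps the two channels exactly.

**3. Voxelization.** The point cloud is translated to its centroid and
isotropically scaled so the farthest point sits at radius `ball_fill`
(default 0.7) inside the unit ball — mass is kept away from the ball
boundary where the truncated polynomial basis degrades. Each point then
deposits its weight (1 for the shape channel, |φ^±| for the electrostatic
channels) onto a `dim`³ grid (default 64). All three channels share one
centering and scaling, so they describe the same frame of reference.

**4. Expansion.** With the orthonormal basis Z_nlm(r, θ, φ) =
R_nl(r) Y_lm(θ, φ), where Y_lm are complex orthonormal spherical harmonics
and

R_nl(r) = sqrt((4π/3)(2n+3)) · r^l · P_k^(0, l+1/2)(2r² − 1), k = (n−l)/2,

(a Jacobi-polynomial radial part, normalized so that (3/4π)∫ Z Z̄ = δ),
the moments and invariants are

C_nlm = (3/4π) Σ_voxels f(v) · conj(Z_nlm(v)) · Δv,
F_nl = sqrt(Σ_m |C_nlm|²).

Truncation at order N = 20 gives (N/2 + 1)² = 121 components per channel.
Moments are computed through the monomial route: each Z_nlm is expanded
once into monomials x^a y^b z^c (cached per order), so all moments become
one complex matrix product with the grid's geometric moments. A direct
per-voxel evaluation of the same basis (Legendre and Jacobi recurrences)
backs the `zernike_reconstruct()` validation path, and the test suite
carries a fully independent explicit-evaluation oracle; the two routes
agree to better than 1e−6 relative error at order 8.

## Comparison statistics

Patches are compared by the Manhattan distance between descriptor vectors.
*Similarity* pairs like channels (shape–shape; mean of pos–pos and
neg–neg). *Complementarity* keeps the shape term and cross-pairs the
electrostatic channels (mean of pos–neg and neg–pos): across a well-formed
interface, one side's positive pattern faces the other's negative pattern.
Both are reported raw (no normalization), with all four electrostatic
pairings available for diagnostics, and small values mean high
similarity/complementarity. No combined single score is defined; the
channels are scientifically distinct and are reported separately.

For ensembles, `pairwise_distances()` builds intra- (all unordered frame
pairs, n(n−1)/2 samples, self-pairs excluded) and inter- (all ordered
pairs, n₁·n₂) distance distributions. Two distributions are compared by
the signed overlap coefficient: Gaussian-kernel densities with Silverman's
rule-of-thumb bandwidth, evaluated on a common 512-point grid spanning the
pooled range extended by 3 bandwidths; the magnitude is ∫ min(f̂₁, f̂₂),
and the sign is + if the first distribution's mean is ≥ the second's
(ties, which are measure-zero in practice, take +). Each density is
renormalized to unit trapezoidal mass *on the evaluation grid* before the
minimum is taken: this makes the overlap a true density-area fraction —
identical distributions score exactly 1 instead of 1 minus the kernel tail
mass lost outside the finite grid — while disjoint distributions still
score ≈ 0. The ensemble channel distance for "elec" is the similarity
average of the pos–pos and neg–neg distances, with per-sign distributions
available separately.

`pca_project()` fits PCA on the pooled mean-centered frames of all
ensembles (a shared projection plane is required for the ensembles to be
compared in one essential space) and reports projections and
explained-variance fractions. The "elec" channel concatenates the positive
and negative vectors so one projection captures both.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `order` | 20 | expansion order; 121 invariants per channel |
| `dim` | 64 | voxel grid edge; resolves order-20 polynomials |
| `ball_fill` | 0.7 | fraction of unit-ball radius for the farthest point |
| `probe_radius` | 1.4 Å | solvent probe |
| `dielectric` | 4 | uniform Coulomb screening |
| `samples_per_atom` | 200 | SAS sampling density |
| `voxel_method` | trilinear | weight deposition rule |
| `binarize_elec` | FALSE | occupancy instead of magnitude for elec voxels |
| `normalize` | FALSE | scale descriptors to unit L2 before comparison |

Radial-polynomial coefficients are exact binomial products evaluated in
double precision; they are well conditioned through order 20, and higher
orders trigger a warning rather than an error.

## Numerical design choices

**Trilinear deposition.** Nearest-voxel accumulation is the simplest
mass-conserving rule, but an order-20 basis probes the grid at the scale
of single voxels, and the lattice noise of nearest-voxel binning breaks
rotation invariance at the several-percent level at dim = 64. The default
is therefore trilinear (cloud-in-cell) deposition — each point splits its
weight over the eight surrounding voxel centers — which is equally
mass-conserving and reduces the invariance error several-fold.
`method = "nearest"` remains available.

**Invariance is a discretization statement.** Translation invariance is
exact by construction (centroid centering). Rotation invariance holds up
to two discretization effects: surface-sampling noise (the sample lattice
is fixed in the laboratory frame, so a rotated structure is sampled at
different surface points, and burial decisions at occlusion boundaries
flicker) and voxel-binning noise. The sampling part dominates and scales
as 1/sqrt(`samples_per_atom`): for the bump fixture at dim 64 / order 20
the worst-of-20-rotations aggregate relative deviation Σ|ΔF|/ΣF falls
from ~6% at 200 samples/atom to ~0.5% at 8000. The invariance test suite
therefore runs at 8000 samples/atom; a perfectly symmetric object (a
single sphere) is exactly invariant at any sampling because the fixed
lattice regenerates the identical point cloud. Individual descriptor
components span four or more decades for realistic patches, so a
*per-component* relative tolerance is meaningful only for components well
above the discretization noise floor (~1e−3 of the leading component);
aggregate deviations are the robust invariance measure.

**Farthest-point scaling.** The unit-ball scale is set by the farthest
sample from the centroid. This makes the scale slightly
sampling-dependent (the sampled maximum underestimates the true one by
O(spacing²)); the error enters all channels coherently and is part of the
sampling-noise budget above.

**Degenerate inputs.** A single surface point is a legitimate delta and
is placed at the grid center; two or more coincident points are rejected
as degenerate. Zero charges yield exactly zero electrostatic descriptors
(not an error). Zero-variance distance samples make the KDE bandwidth
undefined and are rejected with a pointer to exact comparison. The
ensemble driver skips the electrostatic channel entirely when no input
frame carries charges.

## What the synthetic fixtures emulate

The fixture module generates analytic atom sets covering every pipeline
stage without external data: single spheres and ±q dipoles (closed-form
checks), a CA-trace-like helix (100°/residue turn, 1.5 Å rise — a generic
chiral, asymmetric protein-like object), a two-state ensemble (a helix and
a hinge-bent conformer alternating with Gaussian jitter, emulating a
trajectory hopping between states and producing a bimodal
distance-to-reference series), and a complementary receptor/ligand pair.
The pair construction exploits a property of the descriptor: F_nl is
invariant under reflection, so a cavity and the bump that fills it —
built as exact mirror images through the plate plane, with matching rim
and curvature — receive near-identical *shape* descriptors, while a
control bump of mismatched curvature does not. Lining the cavity with +q
and the bump with −q plants the electrostatic cross-match that
complementarity scoring should detect.

What the fixtures do **not** emulate: force-field dynamics (jitter is
isotropic Gaussian), solvent structure, Poisson–Boltzmann screening,
side-chain packing or realistic charge distributions. Passing tests
demonstrate that the descriptor machinery measures what it claims on
controlled geometry; they do not certify biological conclusions on real
trajectories, which additionally depend on sampling quality and charge
assignment.

## Problem sizes used in the test suite

Unit tests run at order 8 / dim 32 / 100 samples per atom, where every
property already manifests; the invariance suite runs the full order-20 /
dim-64 configuration at 8000 samples per atom on four fixture kinds with
20 seeded rigid motions each; oracle agreement is checked at order 8 on
32³ random grids; ensemble statistics use 21–40 frame ensembles. The
acceptance script describes a 21-frame ensemble at the full default
configuration.

## Known limitations

* Electrostatics is a bare Coulomb sum with uniform dielectric — a
  deliberate choice matching the descriptor's need for a sign-split
  spatial pattern, not a quantitative potential; no Poisson–Boltzmann
  solver is included.
* The SAS is point-sampled, not triangulated; areas are represented by
  sample multiplicity, adequate for density-style descriptors but not for
  area measurements.
* Orders above 20 are numerically fragile in double precision and warn.
* PDB parsing is deliberately strict: insertion codes are rejected rather
  than silently merged, and unknown elements must be added to the radius
  table explicitly.
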