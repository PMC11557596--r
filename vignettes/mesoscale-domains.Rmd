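---
title: "Mesoscale heterochromatin domains: model, observables and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale heterochromatin domains: model, observables and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mesochrom` studies how condensed heterochromatin organizes into
mesoscale domains — dense regions tens to hundreds of nanometres across —
from two complementary directions:

* a **Brownian-dynamics polymer model** of a confined chromatin fibre
  whose heterochromatin-like beads cluster under a tunable affinity, with
  the dynamical and structural observables needed to characterize the
  resulting domains (mean squared displacement, overlap function,
  pair correlation in confinement, cluster sizes, separations and
  coordination numbers);
* a **quantification pipeline for soft-X-ray tomography volumes**, where
  the voxel values are linear absorption coefficients (LAC, 1/µm, a
  proxy for local carbon density): thresholding, watershed segmentation,
  missing-wedge-corrected effective diameters, nearest-neighbour and
  pair-correlation statistics, and a multiparametric classification
  stage. A toy tilt-series/SIRT forward model, an FSC resolution
  estimator and a 2D mask registration round out the pipeline so that
  every stage can be exercised end to end on synthetic data.

This vignette records the model, the conventions, the tunable parameters
and the design decisions, so a reader can judge what the package
computes and what its tests do and do not demonstrate.

# The polymer model

## Beads and units

The chromatin fibre is a chain of `N` beads of two types: euchromatin
(EC/A) beads of diameter 18 nm and heterochromatin (HC/B) beads of
diameter 25 nm, mixed 55:45 (A:B) in random sequence along the chain.
Volumetric scaling against a 10 nm nucleosome puts roughly 6 nucleosomes
(~1.2 kbp) in an A bead and 16 (~3 kbp) in a B bead; at these segment
lengths the chromatin persistence length (~30 nm) is exceeded, so no
bending stiffness is included. The smallest domain the model can report
is a tetrahedron of four B beads, which is why 25 nm beads map to a
~50 nm smallest domain and why clusters below 4 members are not
reported.

Reduced units: length in A-bead diameters (σ_AA = 18 nm), energy in
`e = k_B T` (4.28 pN·nm at 310 K), viscosity in units of the
nucleoplasmic viscosity (1.5 cP), and time in
`τ = η σ_AA³ / (η* e) ≈ 2.0 × 10⁻³ ms`. The time unit is exposed as a
configurable field of `unit_system()` because the viscosity of
nucleoplasm is itself uncertain; all dynamical statements in this
package are made in reduced time.

## Interactions

Four terms act (all energies in `k_B T`, lengths reduced; the pair
diameter is the arithmetic mean `σ_ab = (σ_a + σ_b)/2`):

* **Soft Gaussian exclusion** between all pairs,
  `ε_vex · exp(−α_vex r²)` with `ε_vex = 10`, `α_vex = 4/σ_ab²`, cut off
  at `3 σ_ab`. There is no hard core: beads can interpenetrate at a
  finite energy cost, which is the appropriate coarse-grained picture
  for polymer "blobs".
* **FENE bond** between chain neighbours,
  `−12 k r₀² ln[1 − (r/r₀)²]` with `k = 1`, `r₀ = 1.5 σ_ab`. The bond
  diverges at `r₀`; an integration step that overstretches a bond is
  reported as an integration failure rather than silently clamped.
* **Heterochromatin affinity** between B-bead pairs,
  `h_HC(r) = −ε_HC r² exp(−α_HC [d_B − 1/(α_HC d_B) + r²])`,
  cut off at `3 σ_BB`. The sign of the `r²` term inside the bracket is
  the one that gives the attraction a genuine optimal separation; with
  the package default `α_HC = 1/d_B²` (and `d_B = σ_BB`) the constant
  term cancels exactly and the potential reduces to
  `−ε_HC r² e^(−r²/d_B²)`, minimized at exactly `r = d_B` with depth
  `ε_HC d_B²/e`. At the working affinities this puts the pair well at
  0.7–2.1 `k_B T`, which is the regime in which clustering switches on
  between `ε_HC = 2` and `ε_HC = 3` — the property that lets reduced
  affinity model perturbed chromatin states. Both `α_HC` and `d_B`
  remain configurable.
* **Confining wall**: a purely repulsive truncated-shifted Lennard-Jones
  (WCA) term in the distance to the spherical cavity wall, cut off at
  `2^{1/6} σ_i`, with `ε_wall = 1`.

`ε_HC = 3` is the control-condition affinity; 2.5 and 2 represent
progressively disrupted heterochromatin.

## Dynamics and initialization

Beads follow the overdamped Langevin equation with Stokes drag
`γ_i = 3π η σ_i`, integrated by Euler–Maruyama with `dt = 10⁻⁴ τ`:
each coordinate receives drift `F/γ · dt` and a Gaussian increment of
variance `2 k_B T dt / γ` (the dimensionally consistent discretization
of the thermal noise). Halving the step changes steady-state energies by
well under 2% (tested).

The chain is initialized as a random walk inside the cavity with bond
lengths at the pair diameter; soft cores mean overlaps between
non-consecutive beads are acceptable and only immediate re-tracing is
rejected. Initial placement keeps beads outside the wall's WCA range so
the first step is not kicked by an unphysical wall force. Placement
failure after bounded retries (a cavity too small for the walk) is an
error.

## Simulation conditions and the cavity

Two statements about the full-scale system's geometry are in tension: a
reduced bead density `N/V ≈ 0.2` and `N = 3000` beads in a cavity of
diameter ≈ 1 µm (which implies `N/V ≈ 0.033`). They differ by a factor
of ~6 and cannot both hold. The package default for
`cavity_radius` derives from density 0.2
(`cavity_radius_for_density()`), but the **steady-state structure
protocol** used for the headline cluster observables adopts the explicit
3000-beads-in-1-µm geometry, scaled down at fixed bead density to
`N = 500` (cavity radius 15.3 σ_AA ≈ 275 nm). At the denser 0.2 setting
the long-ranged affinity drives all B beads into one or two merged
aggregates within a few τ, which is not the many-domain organization the
model is meant to produce; the dilute, explicitly stated geometry
sustains a population of distinct domains. Both settings are a single
argument away.

Problem sizes used by the tests and the acceptance script: `N = 500`,
three seeds, `4 × 10⁵` steps (40 τ), snapshots every 0.4 τ, with
structural measurements on the trailing quarter of each trajectory.
At strong affinity the potential energy relaxes logarithmically —
a slowly coarsening, glass-like approach to steady state rather than a
clean plateau — so the plateau detector (trailing-window linear fit,
threshold 10⁻⁴ e/τ) typically does not fire within this budget and the
trailing-window convention stands in for "steady state". Over the
measurement window the energy drift is below ~0.005 e/τ and the cluster
count is stable; the residual slow coarsening is a known limitation
discussed at the end.

# Simulation observables

**MSD and overlap.** Mean squared displacement and the overlap function
`Q(t)` (the fraction of beads displaced less than their own diameter
over lag `t`; a displacement of exactly one diameter counts as moved)
are averaged over beads of one type and over all steady-state time
origins; origin averaging is a deliberate statistical improvement over a
single origin and is flagged in the curve metadata. The intermediate-lag
MSD of A beads follows the `t^{1/2}` scaling characteristic of Rouse-like
polymer dynamics; the package measures the exponent over lags of
0.4–4 τ, above the single-bead diffusion crossover and below the
confinement plateau at these problem sizes.

**Pair correlation in confinement.** `g(r)` in a sphere needs no
periodic images but does need the ideal-gas normalization
`ρ · V_shell`, where `V_shell` is the exact intersection of the
spherical shell around each reference point with the cavity — computed
in closed form (the spherical-cap integral) per reference point. The
naive `4π r² δr` normalization is biased low at separations comparable
to the cavity radius; the corrected estimator returns `g ≡ 1` for
uniform points all the way to the boundary (tested to ±0.1). Bins with
zero pair count are reported as missing, not zero.

**Clusters.** B beads within a bond cutoff are "bonded"; beads with ≥ 3
bonded B neighbours are core; clusters are connected components of the
bonded graph over core beads; bonded non-core B beads adjacent to a
component are attached as a "halo". Sizes are reported both ways
(core+halo is the default membership); the volume-equivalent diameter is
`(Σ σ_i³)^{1/3}` in nm over members. The bond cutoff defaults to the
first minimum of the steady-state `g_BB(r)`, searched within the
nearest-neighbour bond shell (`r ≤ 2 σ_BB`); with the very soft cores
used here the clustered phase is a compressed amorphous blob whose
`g_BB` decays monotonically from its principal peak out to the
whole-cluster envelope, so a classical bond-shell minimum often does not
exist and the estimator falls back to `1.5 σ_BB`. A minimum found only
at the cluster-envelope scale (~3 σ_BB) would make entire neighbouring
domains "bonded" and is deliberately excluded by the capped search.

**Coordination number.** Two clusters are neighbours when at least one
chain segment runs from a member of one to a member of the other without
passing through a third cluster; multiple connecting segments count
once. A cluster whose nearest member sits within `σ_BB` of the wall
gains exactly one contact. `z_c` is the neighbour count plus the wall
contact.

# Tomographic quantification

**Threshold.** The mesoscale-domain threshold inside a heterochromatin
mask is `Θ = min(LAC) + 0.6·(max − min)`, computed on raw (undenoised)
masked values. A constant region yields a warning and, downstream, an
empty domain table.

**Segmentation.** Voxels with `LAC ≥ Θ` inside the mask are foreground.
The 3D Euclidean distance transform (separable squared-distance
algorithm) is computed in compiled code, markers are its local maxima
with a minimum separation of 2 voxels, and a priority-flood watershed
assigns basins. Basins whose mutual boundary (saddle) distance value
reaches 0.8 of the smaller peak height are merged — this keeps single
domains with rough surfaces intact while still splitting spheres fused
by a thin neck — and domains below 8 voxels are discarded. All three
thresholds are arguments. No installed package provides a 3D distance
transform or 3D watershed (the available image tooling is framewise
2D), which is why both kernels are implemented here.

**Missing wedge.** Limited-angle acquisition (−65°…65°) elongates
features along z. The correction factor `f_mw = D_rec/D_fid` (fiducial
diameter as reconstructed over truth) is applied as an isotropic volume
multiplier inside the effective diameter
`D_eff = (6 f_mw V_seg / π)^{1/3}`, with z centroids rescaled by `f_mw`
before distance computations. Voxel indices are 0-based with centroids
at `(index + 0.5) × voxel`; the voxel edge default is 13 nm (voxel
volume 2197 nm³).

**Spatial statistics.** k-NN distances (k = 1…10 by default) come from
exact all-pairs sorting. The domain pair correlation reuses the
confinement-corrected estimator; the coordination number integrates
`4πρ_MD r² g(r)` from `r₁` (the mean domain radius — a per-domain
reference radius is the exposed alternative) to `r₂`, the first minimum
of `g` beyond its principal peak. The integral is evaluated bin-wise
with the exact shell volume per bin and `g` constant per bin, which
makes it reproduce per-reference neighbour counts exactly on lattice
test patterns (FCC gives 12 within 5%); the peak search is restricted to
separations below the region radius, where shell statistics are dense.
Smoothing for the edge search defaults to a 3-bin moving average and is
switchable off for clean histograms.

**Size distributions.** Domain diameters are fitted by a maximum-
likelihood skew-normal (direct Nelder–Mead on (ξ, log ω, α) with a
moment start; CDF via Owen's T evaluated by fixed-order Gauss–Legendre
quadrature), with a bootstrap CI on the shape α. Recovery tests: α = 0
data yield a CI covering zero; α = 4 data recover the shape within 25%
at n = 5000.

# Tilt series, SIRT and FSC

The forward model is a parallel-beam projector (rotation about y,
bilinear interpolation in the tilted plane, one-voxel ray steps)
returning both the line-integral sinogram and the Beer–Lambert
intensity. The backprojector applies the identical weights, so the pair
is an exact adjoint (⟨Ax, y⟩ = ⟨x, Aᵀy⟩ to machine precision) — the
property SIRT's convergence relies on. SIRT uses the standard row- and
column-sum normalized simultaneous update
`x ← x + λ C Aᵀ R (b − A x)` with `λ = 1` by default; this normalized
form has a guaranteed non-increasing residual on consistent data (the
residual is monitored and three consecutive increases abort with
diagnostics). A bare `1/N_angles` relaxation without the row/col
normalization was rejected because it does not carry that guarantee.

FSC splits a tilt series into even/odd halves by projection index,
reconstructs each, and correlates Fourier shells; the half-set
correction `FSC' = 2·FSC/(FSC+1)` (monotone on (−1, 1], mapping 1/3 to
0.5) compensates the halved dose, and resolution is reported as the
half-pitch at the first crossing of the criterion — 0.5 on the corrected
curve by default, with 0.143 exposed, since the half-set correction is
conventionally paired with the 0.5 threshold.

# Registration

Light-microscopy and X-ray masks are aligned with an isotropic
similarity transform (scale, rotation, translation about the image
centre). The cost is the mean of the two directed mean boundary
distances, evaluated by bilinearly sampling a precomputed
distance-to-boundary field of each mask — smooth in the parameters,
which lets Nelder–Mead reach sub-pixel optima that a discrete
point-to-point cost cannot. Initialization: scale from mask areas,
rotation from principal second-moment axes (both polarities tried,
because the axis is defined modulo 180°), translation from centroids.
Synthetic recovery is within 0.02 in scale, 1° and 0.5 px; results with
residuals above 5% of the mask diameter are flagged low-confidence.

# Features and classification

Per-region feature vectors combine heterochromatin-wide quantities
(domain count, foreground fraction, LAC moments and skewness, D_eff
moments, skew-normal α, mean k-NN distances for k = 1…10, g(r) first-peak
position, mean z_c) with domain-level quantities (D_eff, volume, LAC
mean/max, 1-NN distance). The exact list is versioned in the output
metadata and configurable; regions with fewer than 4 domains are flagged
unstable, and NN features of single-domain regions are emitted as
missing.

Classification standardizes features (z-score, parameters learned on the
training split only), fits PCA on the training split, keeps the first 12
components (truncated to rank), trains LDA on the scores with a
stratified 60% split (stratification is a deliberate choice: with class
counts of a few dozen an unstratified split can lose a class), and
reports held-out accuracy plus per-class 95% multivariate-t confidence
ellipses (robust centre/scatter via `MASS::cov.trob`, F-quantile
radius). The random-forest validation tunes the tree count on
out-of-bag error, reports held-out accuracy, and retains features whose
permutation importance (mean decrease in accuracy — chosen over
single-feature accuracy as the more standard reading of an "accuracy
score"; the alternative is a one-liner on the returned importances)
exceeds 40% of the maximum. Mann–Whitney U tests back pairwise
treatment-vs-control comparisons and are validated against an exact
pair-counting oracle.

# Synthetic data

The generators exist so every stage is testable without any microscope:

* `generate_phantom()` builds two-phase LAC volumes — dense spherical
  domains (0.15–0.27 µm⁻¹) with truncated skew-normal diameters
  (mean ≈ 80 nm, support 30–250 nm) embedded in a heterochromatin
  surround (0.10–0.15 µm⁻¹) inside a euchromatin background spanning
  0.05–0.22 µm⁻¹. The background draw is left-skewed (a beta(2, 5)
  shape over the printed range) so the region medians order
  dense > surround > background, which a uniform draw over the same
  range would violate. Additive Gaussian voxel noise; optional
  ellipsoidal z-stretch to emulate missing-wedge elongation; exact
  ground truth returned.
* `generate_feature_table()` produces four labelled classes
  (control/TSA/G9a/ROS) with class-mean shifts of `effect_size` pooled
  SDs in distinct sign patterns — effect 0 gives chance-level
  classification, effect 10 gives near-perfect separation, bracketing
  the pipeline.
* `generate_mask_pair()` rasterizes a smooth star-convex blob with
  guaranteed odd harmonics (so rotation is identifiable) and applies a
  known similarity transform with anti-aliased re-binarization.

What the phantoms deliberately do **not** emulate: photon-counting
noise and detector response, reconstruction artefacts other than the
geometric missing wedge, non-spherical or textured domains, nucleolar
and membrane ultrastructure, and the spatial correlation of real
chromatin backgrounds. Passing phantom-recovery tests therefore
demonstrates the correctness of the computational chain, not the
biological fidelity of segmentations of real tomograms. One consequence
worth knowing: with the 60%-of-range threshold rule, domains whose mean
LAC falls below the threshold computed over the whole region are
invisible by construction, so count-recovery tests use phantoms whose
domains all sit above it.

# Numerical choices and degenerate inputs

* Forces are analytic gradients, verified against central finite
  differences to better than 1e−5 relative error.
* All-pairs neighbour evaluation (exact) rather than cell lists: at the
  problem sizes used (N ≤ 3000, cutoff 3 σ comparable to the cavity
  radius) cell lists would buy little and the exactness contract is
  free.
* FENE overextension, non-finite coordinates and empty inputs raise
  errors with the offending bead/step identified; empty foregrounds,
  empty cluster sets and missing mask labels return empty results, not
  errors.
* Ties and plateaus in the distance transform are handled by the
  minimum-separation marker suppression plus saddle merging.
* The equilibration detector is a trailing-window linear fit
  (`|slope| < 1e−4 e/τ`); trajectories without a plateau carry a warning
  record and their steady-state flags stay false.

# Known limitations

* **Finite-size coordination numbers.** At `N = 500` the steady state
  sustains roughly five distinct domains, so a cluster's coordination
  number is bounded by the cluster count and the pooled mean `z_c`
  (~2) sits well below the isostatic value 6 that a full-scale
  (`N = 3000`, ~1350 B beads) system's many-domain packing can reach.
  The chain-link adjacency is also sparser after long coarsening, when
  each domain has absorbed chain-contiguous material. Scaled-down runs
  reproduce domain sizes and separations well, but under-count
  inter-domain contacts; treat small-N `z_c` values as lower bounds.
* **Slow coarsening.** At strong affinity the system is glassy; the
  trailing-window convention measures a slowly evolving (if
  structurally stable) state, and very long runs would coarsen further
  toward fewer, larger domains.
* **Parameter provenance.** The interaction amplitudes are package
  defaults chosen for the documented qualitative regime behaviour; the
  structural observables (domain size ~80 nm, separation ~120–145 nm)
  are robust to them only at the tens-of-percent level.
* The toy projector ignores the optics point-spread function and dose;
  FSC resolutions from it characterize the synthetic pipeline only.
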