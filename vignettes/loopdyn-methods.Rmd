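---
title: "Methods: coarse-grained sampling and loop-dynamics analysis in loopdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained sampling and loop-dynamics analysis in loopdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`loopdyn` characterizes flexible regulatory loops — its motivating case is
the acidic loop 7 of family-3 (Cdc34-like) ubiquitin-conjugating enzymes —
from coarse-grained conformational sampling.  This vignette documents the
models, the parameters that matter, the numerical choices, and what the
synthetic-data closure tests do and do not demonstrate.

## The elastic network

A protein is reduced to its Cα trace; beads carry 100 Da (an average
residue).  Every bead pair `(i, j)` with native distance `r0` interacts
through a harmonic potential `V = K(r0)/2 (r - r0)^2` whose stiffness
follows the Kovacs inverse-sixth-power form

$$K(r_0) = C\,(r^*/r_0)^6, \qquad C = 40\ \mathrm{kcal\,mol^{-1}\,Å^{-2}},
\qquad r^* = 3.8\ \mathrm{Å}.$$

`r*` is the mean consecutive Cα–Cα distance, so directly bonded neighbours
feel the full stiffness `C` and the interaction decays smoothly with
distance — this *replaces* a hard cutoff, and the harmonic samplers
therefore connect all pairs.  The assumption underlying every sampler is
that the input structure is the energy minimum; all fluctuations are
around it, so unfolding, barrier crossing and anharmonic side-chain
physics are out of scope by construction.

### Normal modes (ANM)

The 3N×3N Hessian is assembled from pairwise super-elements
`K/r0² · d dᵀ` (`d` the native inter-bead vector) and diagonalized with a
dense symmetric eigensolver.  Eigenvalues below `1e-8 ×` the largest are
rigid-body modes: six for any non-degenerate 3D network, five for a
collinear two-bead system (the scale-free tolerance makes this count
geometry-driven, not unit-driven).  More than six near-zero modes means
the network is disconnected or degenerate and is an error rather than a
warning — every downstream quantity would silently be wrong.  Note that a
perfectly straight chain is degenerate (the rotation about its own axis
has no restoring force); the synthetic helix, not the extended chain, is
the canonical test geometry for modes.

Ensembles are sampled as
$x = x_0 + \sum_m \sqrt{k_BT/\lambda_m}\, z_m v_m$ with independent
standard Gaussians `z_m` over the non-rigid modes.  The amplitude
convention (variance `k_BT/λ` per mode) is the package's explicit choice
where upstream descriptions leave it open; it is the convention under
which the sample covariance converges to the pseudo-inverse covariance
`k_B T H⁺`, which is exactly what the acceptance checks assert (relative
Frobenius error below 5 % at 20,000 frames on a 5-bead helix).

### Brownian dynamics

BD integrates underdamped Langevin dynamics on the same harmonic network
with the BAOAB splitting: two half-kicks and two half-drifts around an
exact Ornstein–Uhlenbeck velocity update.  BAOAB is exact for the
free-particle and thermostat parts and has excellent configurational
accuracy for harmonic forces at small `ω·dt`; with the stiffest mode at
`ω ≈ 18 ps⁻¹` and `dt = 1 fs`, `ω·dt ≈ 0.02`, discretization bias is
negligible against sampling noise.  No integrator was named upstream; the
BAOAB choice is documented here as the package's own.  Parameters:
friction γ = 0.4 ps⁻¹ (water-like), T = 300 K, 1 fs steps.  The paper-scale
run length is 5,000,000 steps; package defaults are scaled down
(`bd_params()`: 200,000 steps, stride 100) and every run records its
parameters.  Diverging coordinates abort with a message naming `dt`.
Because the potential's exact functional form was published only as a
figure, BD uses the harmonic Kovacs potential; this interpretation is
flagged here deliberately.

The BD↔NMA cross-validation (both covariances against `k_B T H⁺`, 10 %
for BD) is a genuine two-route check: an event-free stochastic integrator
and an eigendecomposition agreeing on the same analytic limit.  The free
diffusion and bond-variance unit tests compare against closed forms
(`MSD = 6 k_BT/(mγ²)(γt - 1 + e^{-γt})`, `var(r) = k_BT/k`).

### Discrete molecular dynamics

DMD replaces springs with infinite square wells: a pair at native distance
`r0` (only pairs within `r_c = 8 Å` in the native structure) is confined to
`[(1−σ) r0, (1+σ) r0]`, with σ = 0.1 and a narrower σ = 0.05 for
consecutive residues so virtual bonds stay near 3.8 Å.  Between events all
beads move ballistically; the next event is the earliest positive root of
`|r_ij(t)| = wall` over all pairs (a quadratic per pair per wall — inner
walls are only reachable for approaching pairs, outer walls always).  At an
event the radial component of the relative velocity is reversed
(equal-mass elastic reflection), conserving total momentum and kinetic
energy to machine precision; both drifts are tracked across the run and
audited (1e-10 and 1e-8 in the acceptance checks).  Numerical safeguards:
positions advance to the event time minus 1e-12 ps so the pair sits
strictly inside its well when reflected (no double-processing of a pair
exactly at a wall), and every stored frame is audited against wall
violations with a 1e-6 Å tolerance — a violation is an error, because the
event loop must make it impossible.  Velocities are initialized
Maxwell–Boltzmann at 300 K (no DMD temperature was stated upstream; 300 K
keeps the three samplers consistent) with the centre-of-mass drift
removed.

## Ensemble analyses

**Superposition.**  Frames are least-squares fitted (Kabsch, with the
reflection guard) onto the running average, iterated twice so the average
is self-consistent.  This is applied before covariances, PCA and DCCM; the
planted-correlation closure tests disable it (`fit = FALSE`) because a
rigid-body fit would redistribute planted single-axis displacements.

**RMSF / B-factors.**  RMSF is computed on the trajectory projected onto
the leading principal components covering at least 70 % of the variance
(the essential space); `filter_fraction = 1` bypasses the projection
exactly.  `B = (8π²/3)·RMSF²` links the two columns everywhere.

**PCA diagnostics.**  Beads have equal mass, so mass weighting is a
constant factor and is omitted.  Cosine content is computed on the
half-sample grid `cos(iπ(t−½)/T)` so a pure half-period cosine scores
exactly 1; RMSIP compares the top-10 eigenvector subspaces of the two
ensemble halves.

**DCCM.**  `C(i,j) = ⟨Δr_i·Δr_j⟩ / sqrt(⟨Δr_i²⟩⟨Δr_j²⟩)` per
non-overlapping window (windows in frames; at a 4 ps storage stride the
reference 1 ns window is 250 frames), displacements relative to the window
mean after superposition; the reported matrix is the window average, with
the per-window Frobenius distance to the average reported as a consistency
diagnostic (no pass threshold is asserted — none is defined).  The
significance mask keeps `|C| > 0.35` at sequence separation `> 10`.  A
zero-variance residue gets correlation 0 with a warning rather than NaN.

**Chained correlations.**  Breadth-first expansion from root residues over
edges with `|C| ≥ 0.5` up to depth 5; a residue's depth is the minimum
edge count from any root.  Determinism under ties: the recorded parent is
the strongest correlation, then the lower residue index.  The property
tests compare the full depth assignment against an independent
adjacency-power oracle on random matrices.

**Hinge prediction.**  The package's concrete rendering of the B-factor
slope-change idea: the profile smoothed with a window of 3 is split at its
median into fixed (low-B) and floppy (high-B) stretches; hinge candidates
are local maxima of the absolute second difference of the raw profile
(the raw profile, because smoothing displaces the curvature maximum of a
sharp step by one residue), scored by that slope change and assigned to
the N- or C-terminal side of the loop.  A profile whose smoothed range is
below 5 % of its mean yields "no hinge detected".

## Geometric classifiers

**Omega loops.**  For each candidate hinge pair the per-frame hinge
Cα distance is monitored; the verdict uses the median-distance frame
(whether the criteria were applied per frame or on averages was left open
upstream — the report shows per-frame fractions *and* the median-frame
verdict).  Criteria: hinge distance within 3.7–10 Å; hinge distance below
2/3 of the longest Cα–Cα span across the segment in the same frame; 6–16
residues strictly between the hinges; no regular α/β secondary structure
inside the loop (turns and short 3₁₀ stretches tolerated).  The verdict is
the conjunction, so relaxing any threshold is monotone; the best pair
maximizes the fraction of frames satisfying the distance criterion.

**Secondary structure.**  A deliberately simplified dihedral-window
assignment (full hydrogen-bond-based assignment is out of scope): with a
backbone, φ/ψ basins for α (φ ∈ [−100,−30], ψ ∈ [−80,−25]), 3₁₀
(ψ ∈ (−25, 30]) and β (φ ∈ [−180,−45], ψ ∈ (45, 180]); runs of ≥ 4 α
residues are H, ≥ 3 3₁₀ residues are G, ≥ 3 β residues are E, shorter
helical stretches T, everything else C.  Cα-only input falls back to the
pseudo-dihedral of four consecutive Cα atoms (|δ| ≈ 50° helical, |δ| >
140° extended), which distinguishes neither 3₁₀ from α nor handedness.

**Conformational states.**  The distance classifier labels each frame by
the distance between the catalytic-Cys centre of mass (side-chain atoms
when all-atom, else its Cα) and the loop Cα centroid: closed < 0.6 nm,
open > 1.0 nm, semi-open between.  Values exactly at a cutoff go to
semi-open, because closed and open are defined by strict inequalities.
The accessibility classifier labels frames independently by relative Cys
side-chain accessibility (< 20 / 20–35 / > 35 %) and additionally reports
the deeply buried < 10 % sub-fraction, honouring both published
descriptions of the closed state; the agreement rate between the two
classifiers is always reported, never assumed.

**Solvent accessibility.**  An own Shrake–Rupley implementation: a
deterministic Fibonacci lattice of 960 points per atom (so results are
reproducible and rotation sensitivity is quadrature-limited), probe
1.4 Å, van der Waals radii by element.  Relative side-chain accessibility
divides by the same algorithm's value for the residue in an extended
Gly-X-Gly tripeptide built by NeRF with ideal peptide geometry
(φ = −139°, ψ = 135°), onto which the residue's own side-chain
conformation is grafted by superposing N/CA/C — self-consistent with the
query geometry rather than taken from literature tables.  Distorted
geometries can therefore slightly exceed 100 %.  Cα-only structures are
rejected with a pointer to the distance classifier.

## Interaction networks

A frame is a salt-bridge contact when the minimum atom distance between
two oppositely charged groups (NZ; NE/NH1/NH2; OD1/OD2; OE1/OE2; charged
termini) is below 0.45 nm, and a hydrophobic contact when side-chain
carbons of {A,V,L,I,M,F,W,P,Y} come below 0.55 nm.  Minimum atom distance
— not centroid — matches common salt-bridge practice and the per-atom
cutoffs.  His is neutral by default (standard pH), switchable.  An angle
screen exists but is off by default: no angular criterion was specified,
so the distance rule is the definition and the screen (N–O–C > 90°) is
opt-in.  Persistence is the contact fraction; records below 20 % are
treated as noise and dropped when building the unrooted, unoriented
interaction graph, and the full persistence histogram is returned so the
signal/noise separation behind that cutoff can be inspected.
Macro-trajectories concatenate the equilibrated portions of replicas with
recorded boundaries, making the pooled persistence the frame-weighted mean
of per-replica persistences by construction; an interaction absent from
one replica is persistence 0 there, which the records make explicit.

## Conservation

Gaps are excluded from column frequencies (the gap fraction is reported,
and majority-gap columns are flagged and consensus as `-`).  Entropy is
`−Σ p log₂ p` (0 for invariant, log₂20 ≈ 4.32 for uniform columns).
Matrix scores are the mean pairwise substitution score over unordered
sequence pairs, normalized to [0, 1] by the matrix extrema;
the weighted variant uses Henikoff position-based weights so duplicated
sequences are down-weighted.  BLOSUM62 and BLOSUM45 come from Biostrings;
the "PET91" option is a PET91-style log-odds matrix derived at load time
from the published Jones–Taylor–Thornton substitution model
(exchangeabilities × equilibrium frequencies, scaled to one expected
substitution per site, exponentiated, and converted to half-bit log-odds)
— a documented substitute, since the modified matrix it stands in for is
not publicly specified.  Whether "average conservation" averages across
methods or matrices is ambiguous; the per-method normalized scores and
their mean are all emitted.

Consensus symbols per column: literal residue at the threshold (0.70 or
0.80), else a pair `(A,B)`, else the smallest reduced-alphabet class
(acidic n = {D,E} < tiny u = {A,G,S} < hydrophobic h, with C and Y in h by
default and configurable), else `x`.  One genuinely open point: a
frequency rule cannot both prefer the pair `(D,E)` and emit the class `n`
for the same 80/20 column, yet both behaviours have precedent; the default
prefers the pair (the more specific symbol) and `class_over_pair = TRUE`
prefers a qualifying class when both pair members belong to it.  Either
way the symbol can only become less specific as the threshold rises.

## Synthetic data: what the closure shows, and what it does not

Each generator plants the quantity its consuming stage must recover:
correlation matrices (with nearest-positive-definite repair recorded),
exact contact fractions, exact state fractions inside disjoint distance
bands (0.30–0.55 / 0.65–0.95 / 1.05–1.50 nm), designed alignment columns,
ideal chain/helix/hairpin/backbone geometries.  All randomness flows
through one explicit seed per call and outputs are bit-reproducible.

Passing these closures demonstrates that the analysis code measures what
it claims — not that real proteins behave like the fixtures.  The
generators emulate the *statistical structure* the analyses assume
(Gaussian fluctuations, deterministic distance bands, exact contact
geometry); they have no solvent, no side-chain packing, no anharmonicity,
and the planted state bands are separated by construction whereas real
closed/open populations overlap near the cutoffs.  Conclusions about real
E2 loops still require real structures, which the same functions accept
through the multi-model PDB reader.

## Problem sizes and tolerances

The verification suite runs at desk scale by design: 5–10-bead networks,
20,000-frame NMA ensembles, 1.2×10⁶ BD steps (1.2 ns), 50 ps DMD runs,
10,000-frame planted ensembles, 10⁵-point Monte-Carlo SASA oracles.
Tolerances pair each stochastic check with its estimator noise (5 % for
the NMA covariance at 20,000 frames, 10 % for BD where the slow-mode
correlation time limits the effective sample count) and each deterministic
check with machine-level bounds (Hessian vs finite differences ≤ 1e-5;
DMD momentum 1e-10, energy 1e-8, walls 1e-6 Å, bounce times 1e-9 ps).

## Known limitations

* Harmonic samplers cannot show barrier-separated open/closed exchange;
  state populations from NMA/BD ensembles reflect fluctuation geometry
  around one minimum.
* The Cα secondary-structure surrogate is coarse; omega-loop criterion 4
  is correspondingly permissive on Cα-only input.
* The accessibility classifier needs all-atom frames; Cα-only ensembles
  get the distance classifier only.
* `read_pdb` targets standard single-conformer protein PDB files: altloc
  resolution keeps the highest occupancy, waters/heteroatoms are dropped,
  mmCIF and nucleic acids are unsupported.
* Multi-chain inputs with duplicate residue numbers should be addressed
  per chain in selections; the state classifier matches the catalytic
  residue by number and errors on ambiguity.
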