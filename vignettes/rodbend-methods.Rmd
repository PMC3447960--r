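---
title: "Methods: hinge, bending and lipid-shell analysis for rod-like receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hinge, bending and lipid-shell analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rodbend` analyses coarse-grained models of rod-like transmembrane receptors
at one backbone particle per residue, and ships synthetic generators that
emulate the statistical structure of such simulations with known ground
truth. This vignette records the models, the parameters that matter, and the
numerical and design choices behind them.

## The synthetic receptor rod

A receptor dimer is idealised as a multi-chain rod: each chain is a straight
line of particles along +z with a rise of 0.15 nm per residue (a canonical
helical rise), and chains sit on a circle around the axis with
nearest-neighbour chain separation 1.0 nm. Defaults are Tsr-like: 500
residues per chain, two chains, a hinge at residue 268 at the HAMP/coiled-coil
junction, and a three-domain annotation (ligand-binding, HAMP, coiled coil)
around that hinge. Chain length is configurable because a single canonical
construct length cannot be assumed; residue numbering is 1-based everywhere,
with unit conversions only at file boundaries (PDB Å ↔ nm).

Helical geometry is deliberately not modelled: every in-scope analysis
depends only on axis geometry and pairwise distances, so helical wobble and
side-chain structure are folded into isotropic Gaussian positional noise
(`noise_sd`, default 0, typical 0.05 nm in tests — small against the 0.15 nm
rise but large enough to exercise estimator robustness).

Bending ensembles rotate every particle above the hinge rigidly about a
random axis perpendicular to the rod axis through the hinge-particle
centroid; the axis is resampled each frame, reflecting the absence of a
preferred kinking direction in the underlying simulations. Angles are drawn
from a truncated gamma distribution parameterised by its mode (default 30°),
an sd-like spread (default 15°) and a hard cap (default 60°): strictly
non-negative, unimodal, right-skewed and bounded, which is the qualitative
shape of observed bending-angle histograms. A wrapped-normal family is
available as an alternative. The generator returns its ground-truth angles
and axes alongside the ensemble so parameter recovery can be tested
end-to-end.

## Hinge localisation by bisection line fitting

For each candidate split residue *i* (at least `min_segment = 10` residues
from each end — closer splits give unstable two-point-ish fits), two
total-least-squares lines are fitted and the count-weighted mean of their
residual MSDs is recorded; the argmin over *i* is the hinge. Two refinements
relative to the most literal reading of "fit two lines to the particles":

* **Chain-centroid pooling (default).** The dimer bends as one body, and its
  axis is the per-residue chain-centroid trace. Fitting raw pooled particles
  of two parallel chains instead adds a constant lateral-offset baseline
  (0.25 nm² for a 1 nm chain separation) to every split's MSD, and the fit
  direction can trade a tilt against that baseline near the kink; on
  idealised rods this biases the argmin 3–4 residues below the true hinge
  even at zero noise. `pool = "particles"` retains the literal variant; for
  a single chain the two are identical.
* **Overlapping split.** The split residue belongs to both arms (low:
  `resid <= i`, high: `resid >= i`): the hinge particle is the joint and lies
  on both lines. With disjoint arms the profile has an exact tie between
  *i = h−1* and *i = h*, because the upper line passes through the pivot.
  With the overlap the zero-noise minimum is unique and exact.

A flat profile (max − min < 1e-6 nm²) reports "no hinge" rather than a
spurious argmin. The profile is computed from prefix sums of per-residue
moments (O(R) plus one 3×3 eigenvalue problem per split); tests verify it
against a naive oracle that refits every split from scratch via SVD.

The bending angle is the unsigned angle in [0°, 180°] between the two segment
axes with signs fixed along increasing residue index (0° = straight); no
bending direction is defined. Histograms use fixed-origin 5° bins; the modal
angle is the midpoint of the highest-count bin, ties resolved to the lower
bin and flagged. Note that a generator mode of 30° sits on a bin edge, so the
recovered modal midpoint is 27.5° or 32.5° depending on sampling — the modal
*bin* always contains 30°.

## Elastic network models

GNM uses the N×N Kirchhoff matrix at cutoff 0.7 nm, ANM the 3N×3N Hessian at
1.3 nm, both with unit springs (eigenvalues are in arbitrary units; only
ratios and shapes are used). Zero modes are |λ| < 1e-8·max λ; decomposition
is always a full symmetric eigendecomposition (the largest routine systems,
N = 1000 / 3N = 1200, take ~1 s, so a partial solver is unnecessary).

Slow-mode hinge detection selects residues whose dominant-mode component
magnitude falls below the 0.1 quantile (the cited criterion of "small
eigenvector values" comes with no number; 0.1 keeps runs narrow), merged into
contiguous runs with each run's minimum-magnitude residue and sign-crossing
count reported. Two subtleties:

* At a 0.7 nm cutoff the two chains of a dimer (1.0 nm apart) are separate
  connected components, so the dominant mode is computed per component and
  per-residue magnitudes are averaged across chains.
* A near-degenerate dominant eigenvalue (relative gap < 1e-6) triggers a
  warning and the RMS of components over the degenerate cluster is used —
  invariant under rotations within the eigenspace, so the result does not
  depend on the arbitrary basis an eigensolver returns.

On a homogeneous synthetic rod the GNM contact graph is an almost uniform
band matrix, so the dominant-mode node sits near the chain centre and the
low-magnitude run is broad (~50 residues at the default quantile); with the
default geometry (hinge 268 of 500) that run covers the mechanical hinge.
This is the expected behaviour of a topology-only model on a homogeneous
rod, not evidence that GNM localises arbitrary hinges: in real structures the
contact density varies by domain and sharpens the node.

A note on ANM degeneracy tests: a zero-noise one- or two-chain rod is
collinear/planar, which turns transverse deformations into spurious zero
modes, and a four-chain square prism has two internal mechanisms at these
cutoffs. The three-chain rod (triangular prism) is the smallest zero-noise
rod with exactly six rigid-body zero modes, and its two lowest non-zero modes
are the transverse bending pair, exactly degenerate by three-fold symmetry —
that is the geometry used to test the rod-bending physics.

## Conformer metrics

Superposition is the standard SVD (Kabsch) construction with reflection
correction; rank-deficient scatters (collinear selections) are an error
rather than an arbitrary choice of rotation. RMSD series superpose each
frame on the reference *using only the selected particles*, so rigid hinge
motion does not inflate within-domain RMSD. Modal RMSDs use 0.02 nm
fixed-origin bins (values are conventionally reported at two decimals in
nm). GROMOS clustering follows the g_cluster procedure: repeatedly take the
unassigned frame with the most unassigned neighbours within the cutoff,
remove its neighbourhood, recount; ties break to the lowest frame id. The
"middle structure" of a cluster is its RMSD medoid — the member minimising
the summed RMSD to the rest — matching the GROMACS convention. Clustering
can be restricted to a time window (e.g. the last 100 ns), with frame ids
always referring to the full ensemble.

Reported modal backbone RMSDs of real receptor domains (~0.4–0.65 nm) derive
from µs-scale simulations and are not reproducible from synthetic data; they
served only to pick realistic noise regimes for the generators, and no test
asserts them.

## Interaction fingerprints

`D[i, t]` is the minimum distance from any particle of query residue *i* to
any partner particle at frame *t*. Contact sets binarise at 0.8 nm by
default (roughly first-shell contact at one particle per residue; the
colour-scale convention of published fingerprints is not numeric).
Interface similarity is the per-frame Jaccard index between the query
frame's contact set and the reference's time-averaged contact set (residues
in contact in ≥ 50% of reference frames); frames where both sets are empty
are flagged undefined rather than scored 1. Vesicle systems are non-periodic
spheres, so no minimum-image convention is applied anywhere.

## Vesicle construction

Species counts come from largest-remainder rounding of the composition
(default 70/20/10 DPPE/DPPG/CL by count of 35,000 — the bookkeeping counts
take precedence over a slightly inconsistent percentage phrasing elsewhere in
the source material), then split between leaflets in proportion to the
leaflet sphere areas with the same fractions in both leaflets. The outer
radius solves 4π(R² + (R−t)²) = N·APL in closed form with bilayer thickness
t = 4 nm. The area per lipid (0.78 nm²) is the one free parameter, calibrated
once so that the default count closes to an outer diameter of ~70 nm; it is
documented as a constant and not fitted to anything else. Cardiolipin is one
record with one headgroup site (analyses count molecules, not charges), and
leaflet membership is by construction, never inferred from distances.

Headgroups are placed on a randomly rotated spherical Fibonacci lattice per
leaflet with small tangential jitter (0.05 nm), re-drawn where the 0.45 nm
minimum separation or a protein footprint is violated; infeasible densities
error out by a hexagonal-packing capacity bound. Protein anchors use the
offset Fibonacci lattice (n = 1, 2 special-cased to pole/antipodal pair);
displaced lipids are re-placed uniformly outside all footprints, preserving
species counts exactly. The default footprint radius is 0.5 nm so that the
1 nm analysis shell around an anchor is an annulus, not empty space.

## Lipid lateral dynamics

Lipid diffusion is Metropolis Monte Carlo on the leaflet spheres: per sweep
each lipid proposes a Gaussian tangent-plane step (default 0.2 nm,
re-projected to its sphere), rejected outright if any same-leaflet headgroup
would come closer than the minimum separation (hard core), otherwise
accepted with min(1, e^(−ΔE/kT)). The energy is a square well: −ε for a
lipid within 1.0 nm of any protein anchor, else 0, with ε in kT (temperature
enters only through ε; thermostat temperatures are metadata). Defaults
ε_CL = ln 2, ε_DPPG = ln 1.5, ε_DPPE = 0 make the shell-to-bulk concentration
ratios relative to DPPE converge to 2 and 1.5 — the Boltzmann factors — in
the non-interacting limit. One sweep means one attempted move per lipid (the
standard Monte Carlo meaning). The inner loop is compiled (Rcpp) with an
incrementally maintained cell list; R's RNG drives everything, so a single
seed reproduces trajectories bit for bit.

Shell enrichment is computed per frame from shell counts with two
conventions: vs-bulk, E_s = (shell fraction of s)/(global fraction of s), and
vs-DPPE, E_s = [n_s/n_DPPE]_shell / [n_s/n_DPPE]_global. Both are always
emitted because published "doubling" statements are ambiguous between them:
with the default composition the vs-DPPE cardiolipin enrichment converges to
e^ε = 2 exactly, while vs-bulk converges to e^ε/⟨e^ε⟩ ≈ 1.67 because the
anionic species compete for the same shell (⟨e^ε⟩ = 0.7 + 0.2·1.5 + 0.1·2 =
1.2). Shell distances are 3-D Euclidean to the anchor by default — the shell
is defined relative to the protein, not along the membrane — with a geodesic
option that combines the arc length on the lipid's own leaflet sphere with
the radial gap in quadrature (so inner-leaflet lipids are never counted
through the bilayer). Steady-state summaries pool counts over the last 50%
of frames, which is far more stable than averaging per-frame ratios.

The mixing statistic is the mean same-species fraction among each lipid's
k = 6 nearest same-leaflet neighbours, compared per species with the
well-mixed expectation (N_sl − 1)/(N_l − 1); the demixing index
observed − expected is ~0 for well-mixed vesicles and approaches
1 − expected under full phase separation. With all ε = 0 the generator
provably has a uniform equilibrium, and tests confirm no spontaneous
demixing — so protein-free vesicles staying mixed is a property the
synthetic model enforces, not a discovery about real lipids.

## What the synthetic layer does and does not show

The generators emulate: rigid single-hinge bending with isotropic noise, a
bounded unimodal angle distribution, sphere-constrained lateral lipid
diffusion with square-well protein affinity, and exact compositional
bookkeeping. They do not emulate: internal domain deformations, correlated
(helical) noise, membrane curvature coupling, electrostatics, lipid tails,
solvent, or kinetics on a physical timescale (Monte Carlo time is not ns).
Passing recovery tests therefore demonstrates that the *analysis* pipeline
is correct and well-conditioned at realistic noise levels — not that the
generators reproduce molecular reality.

## Problem sizes and runtime choices

Test and acceptance workloads are sized for interactive use: bending
ensembles of 5,000 frames (statistics) or 50 frames (hinge recovery) on
500-residue-per-chain dimers; ENM eigenproblems up to N = 1000 (GNM) and
3N = 1200 (ANM); Monte Carlo on a 2,000-lipid vesicle with 4 anchors for
10⁵ sweeps; oracle suites on 8–70-particle instances. The full 35,000-lipid
vesicle builds in well under a minute.

## Known limitations

* The bisection profile assumes a single hinge; multi-hinge segmentation is
  out of scope, as is per-helix kink analysis.
* GNM hinge localisation on homogeneous rods is dominated by chain topology
  (node near the centre); it corroborates rather than localises.
* The Monte Carlo has no hydrodynamics and a hard-core-only lipid–lipid
  interaction; enrichment ratios at high shell densities are mildly
  suppressed relative to the ideal Boltzmann limit.
* PDB/GRO writers emit one particle per residue/headgroup only; mmCIF and
  binary trajectory formats are out of scope.
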