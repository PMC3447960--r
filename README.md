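# rodbend

Analysis toolkit for coarse-grained simulations of rod-like transmembrane
receptors, built around the *E. coli* serine chemoreceptor **Tsr**. A Tsr
homodimer is a ~22 nm rod (periplasmic ligand-binding domain → HAMP linker →
cytoplasmic coiled coil) that, in isolation, undergoes large bending motions
about a hinge at the HAMP/coiled-coil junction. `rodbend` implements the
analysis layer needed to characterise that behaviour and the receptor's lipid
environment, together with synthetic-data generators that produce test
systems with known ground truth.

## What it computes

* **Hinge localisation by bisection line fitting.** For each candidate split
  residue *i*, two total-least-squares lines are fitted to the backbone trace
  below/at and at/above *i*, and the profile
  MSD(*i*) = (n₁·MSD₁ + n₂·MSD₂)/(n₁+n₂) of mean squared perpendicular
  deviations is minimised: argmin MSD(*i*) is the hinge.
* **Bending-angle ensembles.** Per-frame angle θ = arccos(d̂₁·d̂₂) between the
  two segment axes, histogrammed (fixed-origin bins) with modal and maximum
  statistics.
* **Elastic network models.** GNM (N×N Kirchhoff, cutoff 0.7 nm) and ANM
  (3N×3N Hessian, cutoff 1.3 nm) with unit springs; slow-mode hinge
  identification from small dominant-eigenvector components.
* **Conformer metrics.** Kabsch superposition RMSD, per-domain RMSD series
  with modal summaries, GROMOS conformational clustering with RMSD-medoid
  ("middle structure") representatives.
* **Interaction fingerprints.** Per-residue, per-frame minimum distance to a
  binding partner; contact sets; Jaccard interface similarity against a
  reference interface.
* **Vesicle building and lipid dynamics.** A two-leaflet spherical vesicle
  (default 35,000 lipids, 24,500 DPPE / 7,000 DPPG / 3,500 cardiolipin ≈
  70/20/10, outer diameter ≈ 70 nm) with evenly placed protein anchors, plus
  Metropolis Monte Carlo lipid lateral diffusion with species-specific
  protein affinities, and shell-enrichment / lateral-mixing analyses.

## Worked example

```r
library(rodbend)

spec <- rod_spec(noise_sd = 0.05)            # 500-residue dimer, hinge at 268
ens  <- sample_bending_ensemble(spec, bending_distribution(),
                                n_frames = 200, seed = 1)

glance(bisection_msd_profile(ensemble_frame(ens, 1)))
#>   hinge flat  min_msd max_msd n_candidates
#> 1   268 FALSE 0.00256    5.21          482

glance(bending_series(ens))
#>   hinge modal_angle max_angle modal_tie n_frames
#> 1   268        27.5      59.0 FALSE          200
```

The bisection profile recovers the generator's hinge residue (268) exactly;
the bending histogram has its modal 5° bin at the generator's 30° mode and a
maximum below the 60° cap. The same hinge shows up in the slow GNM mode of a
bent conformer:

```r
g <- gnm(bend_at_hinge(build_rod(spec), 268, 30, axis_seed = 1), cutoff = 0.7)
slow_mode_hinges(g)
#>     run resid_start resid_end resid_min n_sign_crossings
#> 1     1         225       274       248                1
```

On the membrane side, a scaled-down vesicle with four protein anchors and the
default affinity model (cardiolipin well depth ln 2, DPPG ln 1.5, DPPE 0, in
kT, over a 1 nm shell) reproduces the expected shell composition:

```r
v    <- place_proteins_evenly(place_lipids(vesicle_spec(2000, seed = 1)), 4)
traj <- run_lipid_dynamics(v, affinity_model(n_sweeps = 30000, seed = 1))
enrichment_summary(shell_enrichment(traj))
#>   species n_shell enrich_bulk enrich_dppe
#> 1 CL          292       1.63         1.90
#> 2 DPPE       1074       0.856        1
#> 3 DPPG        426       1.19         1.39
```

Cardiolipin is about twice as concentrated near the protein as DPPE
(`enrich_dppe ≈ 2`), the Boltzmann factor of its well depth; relative to the
whole bulk the enrichment is e^ε/⟨e^ε⟩ ≈ 1.67 because the anionic species
compete for the same shell. `autoplot()` methods render the profile,
histogram, fingerprint and enrichment series as ggplot objects.

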