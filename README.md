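# dynloop

Lattice Monte Carlo simulation and analysis of the **dynamic loop model**
of mitotic chromosomes: a coarse-grained chromatin fibre that condenses
into a stiff, elastic, rod-shaped chromatid purely through transient
self-cross-linking — no protein scaffold, no imposed helical order.

## The model

The fibre is a Bond Fluctuation Model (BFM) polymer: N monomers on the
cubic lattice, each occupying a 2×2×2 cube of sites (exact excluded
volume), consecutive monomers joined by bonds from the 108-vector family
generated from (2,0,0), (2,1,0), (2,1,1), (2,2,1), (3,0,0), (3,1,0) by
permutations and sign changes.  Single-site moves plus this bond family
preserve the chain topology.  On top of the self-avoiding chain, any
monomer pair (i, j) whose displacement is itself an allowed bond vector
and whose genomic separation satisfies 2 ≤ j − i ≤ c forms a cross-link
with probability p per sweep; each link lives 1 + Poisson(λ) sweeps and
then dissolves.  The two scientifically meaningful parameters are the
cutoff c (maximum loop size) and the emergent mean loop concentration
(active links per monomer).

Analysis follows the standard observables for this class of models:

* **backbones** — disjoint-block or sliding-window centers of mass
  approximating the chromatid axis at coarse-graining level m;
* **directional correlation** K(s) of backbone bond vectors and the
  **persistence length** l_p = ∫ K ds (trapezoid rule, truncated at the
  first non-positive value), with B = l_p·kT the bending modulus;
* **radial monomer density** perpendicular to the backbone, and the
  **thickness** (0.90-quantile of perpendicular distances);
* **compaction ratio** — unlooped fibre contour (N−1)·⟨bond length⟩ over
  mean backbone contour length;
* **force-extension curves** from equilibrium stretching with a constant
  force F on the chain ends (pulling energy −F·|R_ee|), with Young's
  modulus Y = slope/(πr²), cylinder bending modulus B = Yπr⁴/4 and
  Poisson's ratio −d(width strain)/d(extension);
* **integrated autocorrelation times** with self-consistent Sokal
  windowing, for equilibration detection and independent-sample spacing.

All lengths are lattice units, all energies kT = 1.

## Worked example

Condense a 120-monomer fibre with cutoff c = 20 and measure its geometry
(about a minute on one core):

```r
library(dynloop)
params <- dl_params(cutoff = 20, p_form = 0.03, lifetime = 100)
sched  <- dl_schedule(stage1 = 3e5, stage2 = 6e5, sampling = 1e5,
                      stride = 2500, seed = 42)
traj <- dl_run(120, params, sched)
traj
#> <dl_trajectory> N = 120, 40 frame(s), cutoff 20, p_form 0.03, force 0, seed 42

mean(vapply(traj$frames, dl_loop_concentration, 1))
#> [1] 1.40
m <- as.integer(dl_select_coarse_level(traj$frames, c(6, 8, 10, 12, 15)))
m
#> [1] 12
dl_compaction_ratio(traj$frames, m)
#> [1] 6.0
fr <- traj$frames[[40]]
bb <- dl_smooth_backbone(fr, m)
c(length = dl_chromatid_length(bb), thickness = dl_thickness(fr, bb))
#>    length thickness
#>      52.5       3.1
prof <- dl_directional_correlation(lapply(traj$frames, dl_coarse_backbone, m = m))
dl_persistence_length(prof)$lp
#> [1] 14.7
```

Reading: the looping mechanism keeps ~1.4 cross-links per monomer alive
in steady state and folds the 238-lattice-unit fibre into a rod ~52
lattice units long and ~3 in radius — a six-fold lengthwise compaction —
whose axis has a persistence length of ~15 lattice units, i.e. several
times its thickness.  Longer chains at larger cutoffs reach the 10–30
fold compactions of the full study conditions (see the acceptance
script).

The command-line wrapper exposes the same pipeline
(`simulate`, `pull`, `pull-sweep`, `analyze`, `elasticity`, `diagnose`,
`fixtures`):

```sh
Rscript inst/cli/dynloop.R simulate --config run.yaml --out run.traj
Rscript inst/cli/dynloop.R analyze --trajectory run.traj --out tables/
```

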