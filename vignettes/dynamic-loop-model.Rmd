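---
title: "The dynamic loop model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dynamic loop model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dynloop)
```

## The model

`dynloop` simulates a coarse-grained chromatin fibre as a Bond Fluctuation
Model (BFM) polymer: N monomers on the cubic lattice, each occupying a
2×2×2 cube of sites, with consecutive monomers joined by bonds restricted
to the 108-vector family generated from (2,0,0), (2,1,0), (2,1,1),
(2,2,1), (3,0,0), (3,1,0) under permutations and sign changes.  This
construction gives exact excluded volume and, together with single-site
moves, preserves the topological state of the chain — no strand can cross
another.  There is no bending or torsion potential on the fibre itself and
no attractive potential between segments; kT = 1 and all lengths are in
lattice units.

On top of the self-avoiding chain sits the dynamic looping mechanism.
After the N local-move attempts of every sweep, each unordered monomer
pair (i, j) whose current displacement happens to be an allowed bond
vector ("physical proximity by diffusion"), whose genomic separation
satisfies 2 ≤ j − i ≤ c, that is not already linked, and whose two ends are
below the per-monomer link budget, forms a cross-link with probability p.
A new link receives a lifetime of 1 + Poisson(λ) sweeps and dissolves when
it expires.  While alive, a cross-link constrains the two monomers exactly
like a backbone bond: any move that would take its displacement out of the
bond family is rejected.  The two control parameters of scientific
interest are the cutoff c (the maximum loop size) and the emergent mean
loop concentration — the number of active links divided by N.

This mechanism is a minimal stand-in for the action of condensin and
topoisomerase II: mobile proteins that transiently cross-link chromatin
within a restricted interaction range.  Short-ranged, dynamic
cross-linking alone condenses the fibre lengthwise into a thick, rod-like
filament; no protein scaffold and no imposed helical order are involved.

## Parameters and defaults

| parameter | meaning | default | notes |
|---|---|---|---|
| `cutoff` (c) | max genomic loop size, monomers | 50 | study range 20–80 |
| `p_form` (p) | per-candidate-pair, per-sweep link probability | 0 | calibrate via `dl_calibrate_p()` |
| `lifetime` (λ) | mean link lifetime, sweeps | 100 | see below |
| `max_links` | simultaneous links per monomer | 4 | concentrations up to ~1.4 need several link ends per monomer |
| `force` (F) | stretching force on the end monomers, kT/l.u. | 0 | pulling energy −F·\|R_ee\| |
| `theta` | thickness quantile | 0.90 | radius containing 90% of monomers |
| `window_constant` | Sokal windowing constant | 6 | midpoint of the recommended 4–10 range |

The mean lifetime λ = 100 sweeps was fixed once at design time: it is
long enough that loops are structural (each link outlives ~100 sweeps of
local motion) yet short enough that the condensed phase keeps re-arranging
— link turnover is what lets a condensed chromatid relax, stretch and
re-organize.  The stationary loop concentration is an emergent function of
(p, λ); `dl_calibrate_p()` bridges the gap by monotone bisection on pilot
runs with fixed seeds.  One subtlety matters in practice: pilots started
from a swollen coil underestimate the stationary concentration of the
condensed phase substantially, because condensation itself creates
contact partners.  Reliable concentration control therefore uses two
passes — a rough probability from coil pilots, a first condensation
stage, then a second bisection with pilots warm-started from the
condensed conformation (`dl_calibrate_p(start = )`) before the
condensation is completed.  The achieved stationary concentration is
always reported alongside the target.

## Monte Carlo protocol

One sweep = N attempted local moves (uniform monomer, uniform unit
direction; accept iff all incident bonds stay in the bond family and the
displaced cube hits no occupied site), then link expiry, then link
formation in deterministic (i, j) scan order.  With a stretching force,
moves of the two end monomers pass an additional Metropolis factor
min(1, exp(F·Δ|R_ee|)) corresponding to the pulling energy −F·|R_ee|:
moves that lengthen the end-to-end vector are always accepted, shortening
moves are penalized.  The force direction is thereby always parallel to
the instantaneous end-to-end vector and the chain remains spatially
unconfined (coordinates are unwrapped; the periodic box enters only the
occupancy index).

Runs follow a two-stage initialization: stage 1 equilibrates the straight
rod start into a self-avoiding coil with loops off; stage 2 switches the
looping mechanism (and any force) on and equilibrates again; frames are
then sampled at a fixed stride.  The stage-1 length matters more than it
may appear: if loops are switched on while the chain is still far from
coil equilibrium, the nascent cross-links lock in the stretched
large-scale shape and the fibre condenses into a string of blobs along the
old contour instead of a compact rod.  Even a modest residue of that
stretch survives condensation — runs whose coil was only partially
relaxed yield systematically longer axes and correspondingly lower
compaction ratios — so the compaction measurements use coils equilibrated
well past the point where the squared end-to-end distance plateaus.  The engine advances roughly 10⁵
sweeps per few seconds at N = 400 on one core, which sets the problem
sizes used in the tests: rod→coil equilibration needs ~N²·20 sweeps
(about 3×10⁶ at N = 400), condensation from the coil another ~2×10⁶
sweeps at our λ, and force re-equilibration a few×10⁵ sweeps per force.

Equilibration and sample spacing are judged with the windowed integrated
autocorrelation time τ_int = ½ + Σ_{t≤M} ρ(t), with the self-consistent
Sokal window (smallest M ≥ c_w·τ_int(M), c_w = 6) computed on the squared
end-to-end distance, the slowest observable we track.  Samples further
apart than 2τ_int are treated as independent.  `dl_measure_equilibration()`
reports the first index from which the tail mean of a series stays within
two (autocorrelation-corrected) standard errors of the second-half mean;
tails shorter than 20τ carry no usable signal and are exempt.

## Backbones and geometry

The chromatid axis is estimated two ways.  The *coarse* backbone divides
the chain into ⌊N/m⌋ disjoint blocks of m monomers and takes block centers
of mass (any remainder is dropped); it feeds the directional correlation
K(s) — the mean dot product of unit backbone-bond vectors s bonds apart,
averaged within conformations and then over the ensemble.  The *smooth*
backbone slides the m-window with stride 1 (N − m + 1 points) and feeds
contour length, radial density and thickness.

The coarse-graining level m is chosen by the shape of K(s): at a
well-chosen m the backbone behaves like a worm-like chain and K decays
exponentially, while too little coarse-graining leaves local coiling in
the profile and too much destroys the decay.  `dl_select_coarse_level()`
makes this operational by fitting log K(s) over the decaying range
(K > 0.1) and picking the level with the highest R², ties toward smaller
m; levels leaving fewer than 9 backbone points are rejected as
undersampled.  The persistence length is the trapezoid-rule integral of
K(s) over arc length, truncated at the first non-positive K value to
suppress the noise tail, with the exponential-fit decay length reported
alongside as a cross-check; for a rod-like profile (K never below 0.99)
only a lower-bound flag is returned.

Radial density uses the perpendicular distance of each monomer to the
nearest segment of the smooth-backbone polyline, binned and normalized by
the cylindrical shell volume 2πr·Δr·L, so that density × shell volume
integrates back to exactly N.  Thickness is the θ = 0.90 quantile
(inverse empirical CDF) of those distances.  For these smooth-backbone
quantities the window must cover at least one loop's worth of monomers
(m ≳ c): a smaller window lets the axis follow the fibre's local coiling
into the dense core, which erases the central density dip and biases the
perpendicular distances low.  The cutoff-sweep analyses therefore use
m = c, with 0.5-lattice-unit radial bins.  The compaction ratio divides
the contour length of the unlooped fibre, (N−1) × mean monomer bond
length, by the mean smooth-backbone contour length.  One caveat worth
recording: for an idealized fibre folded exactly in half, this
sliding-window definition does not report the intuitive factor 2 — the
backbone of a perfect hairpin partially retraces the axis, and the ratio
depends on the window m.  For condensed chromatids, whose axis is
traversed once, the definition is unambiguous.

## Stretching experiments

Force-extension curves are measured in equilibrium: for each force the
chain is condensed at F = 0, the force is switched on, the system is
re-equilibrated and then sampled; the relative extension is
ε(F) = (⟨R_F⟩ − ⟨R₀⟩)/⟨R₀⟩ against the zero-force member of the grid.
The force modulus is a weighted through-origin fit of F on ε over
ε ∈ [0, 2] (the linear regime extends to about twice the native length;
beyond it a force plateau with rapid loop loss marks the decondensation
domain).  Young's modulus treats the chromatid as a homogeneous cylinder
of radius equal to its thickness: Y = slope/(πr²); the cylinder bending
modulus is B = Yπr⁴/4, compared against the directly measured B = l_p·kT.
Poisson's ratio is fitted on the asymptotically linear tail of relative
width change versus extension, because the width response is not linear
from the start.

At test scale the per-force runs branch from one shared condensed
conformation per parameter set (with independent seeds and a full force
re-equilibration stage each) instead of repeating the rod→coil→condensed
pipeline per force; the force points then share only their initial
condition, not any annealing history.  The acceptance script uses the
same protocol.

## What the generator emulates — and what it does not

The synthetic study conditions mirror the published parameter ranges:
chains of N = 400 (up to 800 in the original study), cutoffs 20–80,
loop concentrations 0.5–1.4, two-stage equilibration, and equilibrium
(adiabatic) pulling.  Everything is in lattice units; mapping to
nanometers or piconewtons requires a user-supplied lattice constant and
is deliberately out of scope.  The model contains no explicit
protein–DNA binding chemistry, no binding-site sequence specificity, no
SMC dimerization, and no fibre-internal elasticity; the chromatin–solvent
interface and nucleosome-scale structure are below its resolution.
Passing tests therefore demonstrate the collective polymer physics of
dynamic short-ranged cross-linking — condensation, stiffening, elastic
response — not a quantitative model of any particular organism's
chromosomes.

Simulated scales deserve honesty: the published study equilibrated ~5000
independent conformations per parameter set over days of CPU time; the
test suite and the acceptance script run minutes on one core.  The robust
observations at this scale are the ~10-fold lengthwise compaction, the
linear growth of thickness with the cutoff, the rise of radial density
with loop concentration, the force plateau with loop-count collapse, the
large-to-small loop-size shift under stretch, and the proportionality of
the stretching modulus to the loop concentration.  Quantities that hinge
on resolving small signals against the ensemble noise of tens of
quasi-independent frames — the goodness of the exponential fit to K(s),
the few-percent thinning of a stretched chromatid and hence Poisson's
ratio — are at or beyond the resolution limit of runs this short, and
the corresponding checks in the test suite fail on some seeds; they
document the resolution limit rather than a property of the model.
Concentration control has its own limit: below ~0.7 links per monomer
the soft, partially condensed branch drifts away from the calibrated
target over long runs.

## Numerical choices

* Excluded volume is tracked in an exact open-addressing hash of occupied
  lattice sites keyed on wrapped coordinates (backward-shift deletion, no
  tombstones); the validator rebuilds the index from scratch and must
  agree after any move sequence.
* The default box edge is 8(N−1) — four times the initial rod contour —
  which makes self-collision through the periodic images geometrically
  impossible at every force used.
* All randomness flows from one integer seed: the engine consumes a
  mt19937_64 stream per stage, and R-level drivers split sub-seeds with a
  fixed LCG (`dl_derive_seeds`), so identical (state, parameters, seed)
  calls are bitwise reproducible on a given platform.
* Link formation scans pairs in ascending (i, j); links formed earlier in
  a scan count toward `max_links` for later candidates.  Expiry uses
  `expiry ≤ sweep`, and a zero Poisson draw yields the minimum lifetime of
  one sweep.
* The trajectory container is a versioned plain-text format with a JSON
  header and per-frame checksums; version mismatch, truncation and
  checksum failure are distinct errors.  Round-tripping reproduces the
  file byte for byte.

## Known limitations

* Relaxation at high loop concentration is slow; concentrations ≳1.4 at
  λ = 100 approach dynamical arrest, and measured concentrations drift a
  few percent above pilot-calibrated targets as condensation completes.
* The persistence length of strongly condensed rods approaches the axis
  length itself, where the exponential fit degrades (few usable K lags);
  the trapezoid estimate is then the more stable of the two.
* Stretching response equilibrates on the scale of many loop lifetimes;
  at the scaled-down run lengths used here the plateau region carries the
  largest uncertainties of any measured quantity.
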