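---
title: "Expression-dependent Dynamic Loop simulation of interphase chromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-dependent Dynamic Loop simulation of interphase chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynloop)
```

## The model

`dynloop` simulates a single interphase chromosome as a coarse-grained,
freely jointed polymer on a cubic lattice. One monomer represents 150 kb of
chromatin — safely above the fibre's persistence length, so treating the
chain as fully flexible at monomer resolution is justified. Chromosome 1
(~245 Mb) and chromosome 11 (~135 Mb) then become chains of N = 1634 and
N = 899 monomers.

The folding mechanism is *dynamic looping*: whenever two non-adjacent
monomers are brought within a cutoff distance by their own diffusive
motion, they may form a transient bond (a chromatin loop). A bond, once
formed, carries a Poisson-distributed lifetime and dissociates when it
expires. There are no long-range forces and no explicit binder proteins;
because formation is probabilistic and strictly local, no interaction
potential is needed. Looping alone condenses the chain into a
territory-like globule and produces the leveling-off of the mean square
spatial distance at large genomic separations that unlooped polymer models
(random walk, self-avoiding walk, fractal globule) cannot reproduce.

Transcription enters through per-monomer *interaction affinities*. Highly
transcribed chromatin is crowded with transcription machinery, which
shields direct fibre–fibre contacts, so affinity is mapped inversely from
expression: with `e_i` the expression level of monomer i,

$$a_i = a_{max} - (a_{max} - a_{min})\,\frac{e_i - e_{min}}{e_{max} - e_{min}},$$

anchoring the most expressed monomer at `a_min` and unexpressed monomers at
`a_max`. The text constrains only these two endpoints; linear interpolation
is the minimal shape through them, and `affinity_profile(mapping = ...)`
is an explicit extension point for rank-based or nonlinear alternatives.
The pair looping probability is the geometric mean

$$p_{ij} = \sqrt{a_i\,a_j},$$

chosen because it is symmetric, vanishes when either side is zero, and
collapses to `p = a` on a homogeneous fibre, so the homogeneous-affinity
control chain has looping probability equal to its affinity. `prod`- or
`min`-type combiners can be substituted (`looping_probability(combiner=)`).

## Lattice dynamics

The engine is a single-site variant of the bond-fluctuation model:

* each monomer occupies one lattice site; excluded volume forbids double
  occupancy (enforced on wrapped coordinates; the lattice of size L = 600
  is periodic, and L is kept far above the radius of gyration so the chain
  never interacts with its own periodic image);
* allowed bond vectors are all displacements with components in
  {−1, 0, +1} except the null vector (bond lengths 1, √2, √3). The precise
  bond set of the original formulation is not recoverable; this minimal
  fluctuation set is declared in `lattice_config()` and all results are
  reported against it;
* a trial move picks a monomer uniformly, then one of the 6
  nearest-neighbour displacements uniformly, and accepts iff the target
  site is free and every bond of the monomer (backbone and loop) remains an
  allowed vector. One Monte-Carlo step (MCS) is N trial moves;
* the loop cutoff equals the maximum bond length √3 — two non-adjacent
  monomers must be at least as close as backbone neighbours can be. On this
  lattice that is exactly Chebyshev distance 1, so candidates are found by
  scanning the 26 surrounding sites through the occupancy map (O(1) per
  move);
* loop formation is event-driven: after each *accepted* move of a
  loop-free monomer, one uniformly chosen loop-free spatial neighbour is
  tested with probability `p_ij`. Each monomer holds at most one loop bond
  at a time — single-partner bonding keeps `p_ij` a pairwise quantity and
  the bookkeeping unambiguous (the alternative of multiple partners is a
  documented extension, not a configuration switch today);
* expired bonds (`expiry <= clock`, inclusive) are dissolved once per MCS
  after the N trial moves;
* backbone bonds never break: strand passage and topoisomerase action
  happen far below the 150 kb scale of one monomer and are not modelled.

All randomness — monomer pick, direction, candidate pick, formation coin,
lifetime — consumes R's RNG stream in that fixed order, so
`(seed, parameters)` reproduces an ensemble exactly, across the R and
compiled layers.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `bin_size_bp` | 150000 | chromatin per monomer (bp) |
| `L` | 600 | linear lattice size (lattice units) |
| `a_min` | 0.01 | affinity of the most expressed monomer |
| `a_max` | 0.065 | affinity of unexpressed monomers |
| `mean_lifetime` | 8000 MCS | mean Poisson loop-bond lifetime |
| `equilibration_mcs` | 2e5 | MCS per equilibration phase |
| `n_conformations` | 1000 | ensemble size |
| `sample_interval` | `"auto"` | snapshot spacing (`2*tau`) |

`a_min = 0.01` and `mean_lifetime = 8000` follow the calibrated
chromosome setup; the maximum affinity was calibrated there against FISH
distance data to lie between 0.06 and 0.07, so the default takes the
midpoint 0.065 (the desk-scale experiments below use 0.07, the top of the
calibrated band). The printed equilibration length of the original setup
is not recoverable; 2e5 MCS per phase is the package default, guarded by a
stationarity diagnostic (below) and fully configurable.

## Equilibration and independent conformations

Each run starts from a chain grown by biased self-avoiding placement and
proceeds in two phases: phase 1 rejects all loop formation, randomising
the starting conformation as a pure self-avoiding walk; phase 2 enables
looping so the bond population reaches its stationary level before any
sampling. `equilibrate(rg_every=)` records `Rg^2(t)` per phase and
`stationarity_p_value()` (Kendall rank correlation of the series tail
against time — a Mann–Kendall trend test via `cor.test`) flags residual
drift; apply it to an approximately decorrelated thinning of the tail,
since the raw series is strongly autocorrelated.

Production snapshots are spaced `ceiling(2*tau)` MCS apart, with `tau`
estimated from `Rg^2(t)`. `autocorrelation_time()` fits
`C(t) = exp(-t/tau)` by least squares on the log scale, through
`C(0) = 1`, over lags up to the first crossing of 0.1 (minimum 5 lags,
non-positive autocorrelations dropped). Two numerical choices deserve
explanation:

* **fit window.** For a genuinely exponential autocorrelation the window
  choice is immaterial (the AR(1) oracle tests pin the estimator to the
  closed form −1/log ρ). But the `Rg^2` autocorrelation of a looped chain
  is multi-exponential: a fast initial decay from local rearrangements
  sits on top of a slow mode set by loop turnover and global shape
  relaxation. A window ending at the conventional 1/e crossing tracks the
  fast part and underestimates — several-fold — the timescale that
  actually governs whether successive snapshots are independent. Extending
  the window to the 0.1 crossing weights the slow tail and restores the
  intended behaviour (lag-1 autocorrelation of `Rg^2` across snapshots
  near e^−2 ≈ 0.135, in expectation);
* **pilot length.** Autocorrelation times estimated from short series are
  biased low and very noisy, so the pilot segment is extended in chunks of
  `pilot_mcs` until it spans at least 400 estimated `tau` and two
  successive estimates agree within 30% (capped at 60 chunks). Even so,
  single-run `tau` estimates retain substantial spread; for production
  work prefer generous `pilot_mcs`, or fix the interval explicitly
  (`sample_interval = <int>`) once `tau` is known for a system.

## Observables

All ensemble observables average per conformation first, then over the
ensemble. Coordinates are unwrapped, so distances are true Euclidean
distances in lattice units.

* **MSD** (`msd_total`, `msd_loci`): mean squared spatial distance between
  monomers at contour separation n, over all positions and conformations;
  the loci-specific variant restricts to chosen pairs as a FISH experiment
  would. The lattice-to-physical factor (`lattice_scaling`) is the
  least-squares match of the simulated curve to an experimental
  (Mb, µm²) table.
* **Loop distribution** (`loop_size_distribution`, `fit_loop_exponent`):
  histogram of active bond lengths `g = j - i` across snapshots. Loop
  probability is proportional to the number of available pairs `(N - g)`;
  dividing that out, the short-loop exponent α is the least-squares slope
  of `log(P(g)/(N-g))` vs `log g` over 0.5–7 Mb (g in monomers × 0.15
  Mb). Snapshot bonds are the primary estimator; a lifetime-weighted
  bond-event log is a different estimator and is not mixed in.
* **Local density** (`local_density_gkde`): per conformation, a 3-D
  Gaussian product-kernel density with Scott's-rule bandwidth per
  dimension (`sd * N^(-1/7)`, recorded in the output), evaluated at the
  monomer positions; the per-monomer density is ensemble-averaged *before*
  correlating with expression. Region volumes are inversely proportional
  to mean densities, giving the volume ratio
  `V_high/V_low = rho_low/rho_high`.
* **Shape** (`gyration_tensor`, `asphericity`, `shape_metrics`): the
  centred second-moment tensor Q with `trace(Q) = Rg^2`; from its
  eigenvalues the normalised asphericity
  `A = [(λ1−λ2)² + (λ2−λ3)² + (λ3−λ1)²] / [2(λ1+λ2+λ3)²]`, the unique
  standard form that is 0 for spheres, 1 for rods, and scale invariant.
* **Radial position** (`radial_metrics`): per conformation, squared
  distance of each monomer to the chain centre-of-mass and to the
  territory surface. The surface is the convex hull of the monomer
  positions — parameter-free and deterministic; for an interior point of a
  convex polytope the distance to the boundary is exactly the minimum over
  facet-plane distances, which is what is computed (an α-shape surface is
  a possible refinement for strongly non-convex conformations).
* **Mobility** (`msmd`): mean square monomer displacement *relative to the
  chain centre-of-mass*, over time origins of a dense trajectory stream —
  mobility inside the territory, insensitive to territory drift. 5% of
  monomers at each chain end are excluded by default (chain ends diffuse
  differently). The diagnostic `MSMD(t)/t` is constant for normal
  diffusion; its decay exposes the anomalous, confined diffusion of
  territory chromatin.
* **Correlations** (`correlate_with_expression`): Pearson and Spearman
  with two-sided p-values (asymptotic Spearman p, as monomer-level data
  tie freely).

## What the synthetic generator does and does not emulate

`synth_expression_profile()` produces what the simulator actually consumes
from real microarray tables: a per-monomer expression level with
contiguous highly and lowly expressed blocks (position, width and height
of expression domains), truncated-Gaussian noise, and a matching high/low
region annotation (blocks labelled against the profile median). It does
not emulate probe-level artefacts, normalisation effects, unmappable gaps,
or the long-tailed level distributions of real profiles — so tests passing
on synthetic profiles validate the mechanics of the pipeline and the
direction of expression–structure coupling, not quantitative agreement
with any particular chromosome. The desk-scale two-block experiment
(N = 300, `a_min` 0.01 / `a_max` 0.07, lifetime 2000 MCS, ≥200
conformations) recovers the qualitative signature: density anticorrelates
with expression, distance-to-centre correlates positively, the high/low
volume ratio exceeds 1, and highly expressed monomers have larger MSMD.
Full quantitative values (volume ratios ~1.4–1.5, loop exponents −1.1 to
−1.3, |r| up to ~0.7) belong to full-chromosome runs: real expression
profiles, N up to 1634, ≥1000 decorrelated conformations, and external
FISH tables for the µm scaling.

## Degenerate inputs and tie-breaks

* A constant expression profile with `a_min != a_max` is an error (the
  mapping is undefined); request a homogeneous fibre explicitly with
  `a_min == a_max`.
* Monomers not covered by any expression bin get level 0, i.e. `a_max` —
  unannotated chromatin is treated as unexpressed.
* Bond expiry is inclusive: a bond with lifetime 0 forms and dissolves
  within the same MCS, never surviving it.
* `asphericity` clamps tiny negative eigenvalues from numerical
  eigen-decomposition; all-zero eigenvalues are an error.
* The convex hull requires genuinely 3-D point sets; collinear or coplanar
  conformations (impossible for equilibrated chains of any length) raise
  an error rather than a fabricated surface.
* When the autocorrelation is non-positive from lag 1 (white-noise-like
  series), `tau` is reported as 0.5 — below one sampling interval —
  rather than from an unstable fit.

## Problem sizes used in the shipped checks

The test suite runs entirely at desk scale: oracle comparisons on chains
of ≤50 monomers, the excluded-volume scaling control at N = 200 (exponent
pooled over six replicate runs, fit over contour separations 4–50), the
condensation control at N = 200 with homogeneous affinity 0.065, and the
two-block expression experiment at N = 300 with 200 conformations. These
sizes were chosen so the full suite completes on one CPU in minutes while
leaving each statistical check with comfortable power; every full-scale
quantity remains a function call away with the same code paths.

## Known limitations

* Single chains only: no inter-chromosome intermingling, no confining
  nucleus, so whole-chromosome asphericities run below values observed for
  territories packed among neighbours.
* The affinity map and looping-probability combiner are modelling choices
  constrained only at their anchors; both are pluggable.
* Contact information is summarised as the loop-length distribution; no
  Hi-C matrix construction or normalisation is attempted.
* `tau` estimation is intrinsically hard for slowly relaxing systems;
  treat automatic intervals as estimates and check the lag-1
  autocorrelation of `Rg^2` across the saved snapshots when it matters.
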