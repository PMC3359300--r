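# dynloop

Expression-dependent Dynamic Loop simulation of interphase chromatin.

Interphase chromosomes fold into compact chromosome territories, and their
internal organisation tracks transcription: highly expressed regions are
decondensed, sit near the territory surface and are more mobile, while
silent chromatin is dense and central. `dynloop` simulates this with a
coarse-grained lattice polymer (one monomer per 150 kb of chromatin) in
which spatially proximal monomers form *transient loop bonds*. The looping
machinery is driven by a gene-expression profile: each monomer carries an
interaction affinity

```
a_i = a_max - (a_max - a_min) * (e_i - e_min) / (e_max - e_min)
```

so the most expressed locus gets the minimum affinity `a_min` and silent
loci get `a_max`. When two non-adjacent monomers come within the loop
cutoff (the maximum bond length, sqrt(3) lattice units), a bond forms with
probability `p_ij = sqrt(a_i a_j)` and persists for a Poisson-distributed
lifetime (mean 8000 Monte-Carlo steps by default). The chain evolves by
single-site moves on a periodic cubic lattice (L = 600) with excluded
volume — a single-site variant of the bond-fluctuation model — and
observables are averaged over ensembles of conformations sampled every
`2*tau` MCS, with the autocorrelation time `tau` of `Rg^2(t)` estimated by
an exponential fit.

The observable suite covers everything used to characterise the simulated
territories: mean square spatial distance (MSD) vs genomic separation and
its large-separation "leveling-off", loci-specific MSD (FISH-style),
loop-size distributions `P(g) ~ (N - g) g^alpha` with the short-loop
exponent fitted over 0.5–7 Mb, local chromatin density by 3-D Gaussian
kernel density estimation, volume ratios of highly vs lowly expressed
regions, gyration-tensor asphericity (0 = sphere, 1 = rod), squared
distances to the territory centre-of-mass and to its (convex-hull) surface,
mean square monomer displacement (MSMD) in the centre-of-mass frame, and a
least-squares scaling of lattice units to micrometres against experimental
MSD tables.

Who is it for: anyone studying the interplay of transcription and 3-D
genome architecture who wants a mechanistic, entropy-driven null model —
no specific binder proteins, no imposed long-range potentials, just local
contacts with expression-dependent propensity.

## Worked example

A two-block synthetic chromosome — 150 highly expressed monomers followed
by 150 silent ones — simulated at the calibrated parameters:

```r
library(dynloop)

syn <- synth_expression_profile(
  300, data.frame(start = c(1, 151), end = c(150, 300), level = c(10, 1)),
  noise_sd = 0.5, seed = 42)
aff <- affinity_profile(syn$expression, a_min = 0.01, a_max = 0.07)
prm <- sim_params(N = 300, L = 600, a_min = 0.01, a_max = 0.07,
                  mean_lifetime = 2000, n_conformations = 200,
                  trajectory_every = 25, trajectory_frames = 1200, seed = 7)
res <- simulate_chromosome(aff, prm, verbose = TRUE)
#> equilibrating: 2 x 2e+05 MCS
#> production: 200 conformations
#> sampled every 12839 MCS (tau = 6419); 138 loops active at the end

dens <- local_density_gkde(res$ensemble)
correlate_with_expression(dens$density, syn$expression)
#>     method   estimate      p_value
#> 1  pearson -0.5433371 1.933869e-24
#> 2 spearman -0.5564211 8.739651e-26

volume_ratio(dens, syn$regions)
#> [1] 1.043532

rad <- radial_metrics(res$ensemble)
correlate_with_expression(rad$center_sq, syn$expression)
#>     method  estimate      p_value
#> 1  pearson 0.4729893 3.958831e-18
#> 2 spearman 0.5207514 2.980414e-22

curves <- msmd(res$trajectory, syn$regions, edge_exclusion = 0.05,
               max_lag_frames = 40)
aggregate(msmd ~ region, data = curves, FUN = function(x) round(mean(x), 2))
#>   region msmd
#> 1   high 3.13
#> 2    low 2.66
#> 3  total 2.90

fit_loop_exponent(loop_size_distribution(res$ensemble))
#> [1] -0.993 (attributes: 43 fitted points over 0.5-7 Mb)
```

Reading the output: expression anticorrelates with local density (silent
chromatin is denser), correlates positively with squared distance to the
territory centre (active chromatin sits at the periphery), the volume
ratio of highly to lowly expressed chromatin exceeds 1 (active chromatin
is decondensed), active monomers cover more ground inside the territory
(MSMD), and the short-loop distribution decays with an exponent near −1.
These are the qualitative signatures expected of transcription-coupled
territory organisation; their full-chromosome quantitative counterparts
(e.g. volume ratios 1.4–1.5, loop exponents −1.1 to −1.3) require real
chromosome-scale expression profiles, N up to ~1600 monomers and ≥1000
decorrelated conformations.

## Command line

```sh
exec/dynloop synth-profile --config run.yaml   # synthetic profile + regions
exec/dynloop simulate      --config run.yaml   # ensemble (+ trajectory)
exec/dynloop analyze       --config run.yaml   # msd/loops/density/shape/
                                               # radial/msmd/correlations tables
```

The YAML config has `synth`, `simulate` and `analyze` sections (see
`?read_run_config`); unknown keys are rejected, every output embeds its
provenance, and a fixed seed reproduces ensembles byte for byte.

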