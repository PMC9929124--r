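# patchcomm

Long-term fertilization experiments in plant communities show three
remarkably consistent trends: species richness declines, the formerly
dominant species are displaced by species that were rare or absent, and the
rank abundance diagram (RAD) becomes steeper (the community becomes less
even). `patchcomm` implements a minimal mechanistic model that reproduces
all three trends from interspecific competition alone, for theoretical
ecologists who want to study how a fecundity change propagates through a
competitive hierarchy into community structure.

## The model

The habitat is a large set of sites, each empty or held by a single species.
Species are indexed by competitive rank *i* = 1..*n* (1 = best competitor)
and interact by **displacement competition**: when a propagule of a superior
competitor lands on an occupied site, it takes the site. Site-occupancy
frequencies *p<sub>i</sub>* follow Levins-type colonization dynamics

dp<sub>i</sub>/dt = q f<sub>i</sub> p<sub>i</sub> (1 − Σ<sub>j≤i</sub> p<sub>j</sub>) − q (Σ<sub>j&lt;i</sub> f<sub>j</sub> p<sub>j</sub>) p<sub>i</sub> − m p<sub>i</sub>,

with basal colonization rate *q*, disturbance (extinction) rate *m*, and
per-species fecundity *f<sub>i</sub>*. Competitive ability is paid for by
reduced fecundity through a saturating **competition–fecundity trade-off**

f<sub>i</sub> = α (1 − e<sup>−βi/n</sup>) / (1 + e<sup>−βi/n</sup>) = α tanh(βi/2n),

where α is the maximum fecundity and β the saturation intensity.
Because each species' equilibrium depends only on its own fecundity and on
its superiors, the closed-community equilibrium is obtained by a single
forward recursion over ranks, with species dropped to zero whenever

p<sub>i</sub>\* = 1 − Σ<sub>j&lt;i</sub> p<sub>j</sub>\* − (Σ<sub>j&lt;i</sub> f<sub>j</sub> p<sub>j</sub>\* + m/q) / f<sub>i</sub>

is non-positive; a species can appear at all only if f<sub>i</sub> &gt; m/q.
**Fertilization** is modelled as a switch of (α, β) at a scheduled time:
richer conditions raise every species' fecundity (larger α) but most
strongly for species whose fecundity was environmentally limited, which
saturates the trade-off (larger β).

The package provides the trade-off constructors (`tradeoff_params`,
`fecundity_profile`, presets `f0`/`f1`/`f2`, random fluctuation), the
equilibrium recursion (`solve_equilibrium`), the transient dynamics with an
exact fertilization event and weak immigration (`simulate_community`,
via `deSolve`), RAD construction and labeled-SAD bookkeeping (`build_rad`,
`richness`, `compare_communities`, `rad_slope`), and experiment drivers
(`run_fertilization_scenario`, `sweep_alpha_beta`,
`decomposition_experiment`, `fluctuation_experiment`), plus CSV/JSON
serialization and a command-line front end (`inst/cli/patchcomm`).

## Worked example

The baseline community uses the trade-off `f0` (α = 2, β = 4); fertilization
switches it to `f1` (α = 3, β = 16). Community rates are q = 0.3, m = 0.2
with a pool of n = 80 potential species:

```r
library(patchcomm)
params <- community_params(q = 0.3, m = 0.2)
eq0 <- solve_equilibrium(preset_profile("f0"), params)
eq1 <- solve_equilibrium(preset_profile("f1"), params)
eq0
#> Equilibrium: 50 of 80 species at positive frequency, occupied fraction 0.412003
eq1
#> Equilibrium: 49 of 80 species at positive frequency, occupied fraction 0.528595

cmp <- compare_communities(eq0$frequencies, eq1$frequencies, k = 8)
cmp
#> Community comparison: 48 -> 31 detectable species (8 new, 25 lost, 23 retained)
cmp$top_k_tracking
#>   species_index before_rank after_rank
#> 1            15           1          7
#> 2            17           2          9
#> 3            19           3         10
#> 4            21           4         11
#> 5            23           5         12
#> 6            25           6         13
#> 7            27           7         15
#> 8            29           8         17

rad_slope(build_rad(eq0$frequencies))$slope   # -0.0823
rad_slope(build_rad(eq1$frequencies))$slope   # -0.1377
```

Reading these numbers: at the 10⁻⁵ relative-abundance detection threshold
the community drops from 48 to 31 detectable species after fertilization;
8 of the 31 are species that were undetectable before (more-competitive,
low-fecundity species that the steeper trade-off now lets persist); every
one of the previous top-8 species is pushed down the ranking (reordering);
and the log₁₀-abundance-versus-rank slope steepens from −0.082 to −0.138
(evenness falls from 0.79 to 0.49). Total occupancy — the model's biomass
proxy — rises from 0.41 to 0.53. These are the three classic fertilization
trends, produced purely by the competitive hierarchy.

Transient behaviour and the full experiment bundle:

```r
cfg <- scenario_config(before = "f0", after = "f1")  # event at t = 10,000
bundle <- run_fertilization_scenario(cfg)
write_bundle(bundle, "runs/f0_to_f1")                # CSVs, JSON, manifest
```

or from a shell:

```sh
Rscript inst/cli/patchcomm scenario --before f0 --after f1 --out runs/f0_to_f1
Rscript inst/cli/patchcomm sweep --alpha-min 1.5 --alpha-max 4 --alpha-steps 26 \
    --beta-min 2 --beta-max 24 --beta-steps 45 --out runs/surface.csv
```

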