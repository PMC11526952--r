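# gdforecast

Habitat destruction erodes genetic diversity within species, but with a lag:
a population that loses half its range today keeps most of its nucleotide
diversity for a while, then drifts toward a much poorer equilibrium over
thousands of generations. Conservation indicators (Red List categories,
Living Planet Index declines, Global Biodiversity Framework genetic
indicators) measure area and abundance, not DNA. `gdforecast` bridges the
two: it forecasts within-species nucleotide diversity (π) on lattice
landscapes under habitat-loss scenarios and translates indicator tables into
short-, medium- and long-term diversity-loss estimates. It is written for
population geneticists and conservation scientists who want quantitative,
reproducible forecasts from minimal demographic inputs.

## The model in brief

A species is a Wright-Fisher metapopulation on a grid of demes (N diploids
each, 4-neighbour migration at backward rate m, infinite-sites mutation at
rate μ). The expected pairwise diversities π_ij between demes obey a linear
ODE system,

    dπ_ij/dt = 2μ − δ_ij π_ii/(2N) + Σ_k m_ik (π_kj − π_ij) + Σ_k m_jk (π_ik − π_ij),

so equilibria are sparse linear solves and transients are matrix-exponential
actions — no forward simulation needed for expectations. Habitat loss is a
row/column deletion; the restricted system then relaxes to the reduced
landscape's equilibrium. Classical anchors hold exactly: one deme gives
π = 4Nμ; two demes give π_w = 8Nμ and π_b = 8Nμ + μ/m. Around this core the
package provides scenario operators (edge contraction, random fragmentation,
gradual loss, restoration), landscape fragmentation metrics, a forward
Wright-Fisher simulator used as a Monte Carlo oracle, mutations-area /
genetic-diversity-area power laws (M = cA^z, loss = 1 − A^z) with in-silico
extinction curves on geo-referenced genotype panels, and the
indicator-to-loss projection pipeline with precomputed (F_ST × area-loss ×
horizon) tables.

## A worked example

Tune a 10×10 landscape to moderate structure (F_ST = 0.3) at θ = 10⁻⁴, then
remove half the range from its western edge:

```r
library(gdforecast)

lat <- build_lattice(10, 10)
p   <- gd_params(mu = 1e-8, deme_size = 25)    # theta = 4*2500*1e-8 = 1e-4
m   <- tune_migration(lat, p, target_fst = 0.3)
p$mig <- as.numeric(m)                          # 0.0152, achieved F_ST 0.300

run_scenario(gd_scenario("edge_contraction", 0.5), lat, p)
#> Scenario trajectory (edge_contraction, realized loss 50.0%, 1 component)
#>   horizon  time species_loss local_loss
#> 1   short     0        3.79%      0.00%
#> 2  medium  2200       24.94%     25.29%
#> 3    long 13800       49.94%     50.00%
```

Read it as: immediately after losing 50% of its habitat the species has lost
only 3.8% of its species-wide π (the lag — surviving allele frequencies are
untouched); 2,200 generations later drift has taken ~25%; the reduced
landscape's equilibrium sits at ~50% loss, tracking the area loss. Under
*fragmentation* the same machinery shows the opposite signature (the Wahlund
effect): pooled π inflates while within-deme π collapses — compare
`species_loss` and `local_loss` from
`run_scenario(gd_scenario("fragmentation", 0.9), lat, p)`.

Indicator tables plug into the same model through loss tables:

```r
tab <- build_loss_table(fst_grid = c(0.05, 0.2, 0.45),
                        loss_grid = c(0, 0.25, 0.5, 0.75, 0.95),
                        params = p)
records <- synth_species_table(seed = 1)        # or read your own CSV
project_species(records, tab, seed = 1)
```

A command-line interface wraps the same functions
(`exec/gdforecast solve|scenario|table|project|synth|powerlaw|oracle
--config cfg.yaml --seed 1 --out dir`); every run writes tidy CSVs plus a
JSON manifest with the config and seed.

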