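# spatcoex

Spatially explicit simulation of microbial coexistence through
metabolite-mediated interactions.

## The problem

Whether a spatially structured habitat helps or hurts microbial
coexistence, relative to a well-mixed one, depends on how species
interact. `spatcoex` is for ecologists and systems biologists who want to
probe that question with a *mediator-explicit* model: species never
interact directly, only through diffusible chemicals they produce and
consume. Each mediator can facilitate or inhibit the growth of the species
it influences, so the community is a random bipartite network of
production, consumption and signed influence.

On a 1D habitat `z ∈ [0, Z]` the model couples species densities `S_i`
and mediator concentrations `C_j`:

    dS_i/dt = D_cell ∂²S_i/∂z² + (1 − Σ_k S_k / k_Y) ·
              [ r0_i + Σ_j ρ_ij g_ij(C_j) ] · S_i
    dC_j/dt = D_med  ∂²C_j/∂z² + Σ_i (β_ji − α_ji) S_i

with no-flux boundaries, a saturating response `g = C/(C + k_sat)` for
facilitative influences (`ρ > 0`) and a linear response `g = C/k_sat` for
inhibitory ones (`ρ < 0`). Communities start as adjacent single-species
blocks at low density and undergo serial enrichment: grow to a dilution
threshold (10³-fold growth ≈ 9.97 generations per round), dilute
everything preserving the spatial distribution, repeat for 100
generations. *Richness* counts species that finish above the extinction
threshold with a relative frequency that declined less than 10% over the
final 20 generations. A well-mixed counterpart, an infinite-dispersal
limit, ensemble sweeps with bootstrap CIs, and initial-arrangement
shuffling experiments are built in.

## Worked example

```r
library(spatcoex)

net <- generate_network(fac_ratio = 0.9, seed = 11)  # 90:10 fac:inh pool
net
#> Interaction network: 10 species, 5 mediators (seed 11)
#>   production links: 34, influence/consumption links: 24
#>   facilitative: 22, inhibitory: 2, self-facilitation: 14
#>   basal growth rates: 0.108-0.192 /hr

run_enrichment(net, sim_config(), mode = "spatial")
#> Enrichment result (spatial mode, network seed 11)
#>   11 rounds, 109.6 generations, 354.8 hr simulated
#>   richness (stable): 2   present: 5   Shannon: 0.695

run_enrichment(net, sim_config(), mode = "well_mixed")
#> Enrichment result (well_mixed mode, network seed 11)
#>   11 rounds, 109.6 generations, 391.0 hr simulated
#>   richness (stable): 2   present: 5   Shannon: 1.087
```

The mostly facilitative pool of ten species collapses to a handful of
survivors over eleven growth–dilution rounds; five species remain above
the extinction threshold but only two also pass the frequency-stability
criterion, giving richness 2. Ensemble versions of this comparison are one
call away:

```r
sw <- sweep_richness(list(fac_ratio = c(0.1, 0.5, 0.9)), n_instances = 30,
                     master_seed = 42, modes = c("spatial", "well_mixed"))
sw$aggregates   # mean richness ± bootstrap 95% CI per condition and mode
plot(sw)
```

Mean richness rises with the facilitation:inhibition ratio in both modes,
and spatial communities exceed their paired well-mixed counterparts when
facilitation dominates — the package's ensembles share network seeds
across conditions, so every contrast is paired.

A thin command-line wrapper lives at `inst/scripts/spatcoex-cli.R`
(subcommands `simulate`, `sweep`, `network`) for driving the same
functions from a shell.

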