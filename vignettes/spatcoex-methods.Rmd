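---
title: "Methods: spatial mediator-explicit community simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial mediator-explicit community simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spatcoex)
```

## The model

`spatcoex` simulates communities of microbial species that interact only
through diffusible chemical mediators. Species $i$ has spatiotemporal
density $S_i(z,t)$ (cells/ml) on a one-dimensional habitat $z \in [0, Z]$;
mediator $j$ has concentration $C_j(z,t)$ (fmol/ml). The dynamics are

$$\frac{\partial S_i}{\partial t} =
  D_{cell}\frac{\partial^2 S_i}{\partial z^2} +
  \Big(1-\frac{\sum_k S_k}{k_Y}\Big)
  \Big[r_{0,i} + \sum_j \rho_{ij}\, g_{ij}(C_j)\Big] S_i$$

$$\frac{\partial C_j}{\partial t} =
  D_{med}\frac{\partial^2 C_j}{\partial z^2} +
  \sum_i (\beta_{ji} - \alpha_{ji})\, S_i$$

with no-flux boundaries at $z = 0$ and $z = Z$ for both fields. A mediator
influence is *facilitative* ($\rho_{ij} > 0$), with a saturating response
$g_{ij}(C) = C/(C + k_{sat})$, or *inhibitory* ($\rho_{ij} < 0$), with a
linear response $g_{ij}(C) = C/k_{sat}$. Influences add on top of the basal
growth rate $r_{0,i}$, and the logistic crowding factor $(1 - \sum_k
S_k/k_Y)$ multiplies the whole bracket. Production ($\beta_{ji}$) and
consumption ($\alpha_{ji}$) are proportional to producer/consumer density;
consumption accompanies every influence link regardless of sign, so a
species draws down inhibitors it is sensitive to just as it draws down its
growth substrates.

Communities are random: production links exist with probability $q_p$ per
(mediator, species) pair, influence/consumption links with probability
$q_c$; rates are uniform on $[0.5, 1.5]$ times their set values
($\beta_0 = 0.1$, $\alpha_0 = 0.15$ fmol cell$^{-1}$ hr$^{-1}$); influence
magnitudes are uniform on $(0, r_{int,0}=0.2)$ /hr with sign facilitative
with probability `fac_ratio`; basal rates are uniform on $[0.1, 0.2]$ /hr.
`generate_network()` draws all of this in a fixed order with a fixed draw
count, so networks generated under different `fac_ratio` from one seed
differ *only* through influence signs — the common-random-numbers pairing
that every sweep in the package exploits.

## Numerical scheme

The three processes run on separate clocks (asynchronous updates):

* growth and mediator production/consumption every `dtau` = 0.01 hr;
* mediator diffusion every `dt` $= 0.1\,dz^2/D_{med}$ (≈ 1.4 × 10⁻⁴ hr at
  defaults, i.e. 72 diffusion sub-steps per growth step);
* cell dispersal every `dc` $= 0.1\,dz^2/D_{cell}$ (≈ 500 hr at defaults —
  dispersal events essentially never fire at the default $D_{cell}$).

When events coincide the order is growth → mediator diffusion → cell
dispersal; the choice is arbitrary but fixed, and differences are of the
order of one sub-step. Diffusion uses the standard explicit
second-difference stencil with reflecting boundaries, which conserves mass
to machine precision and preserves nonnegativity for
$\lambda = D\,dt/dz^2 \le 0.5$ (the package refuses prefactors above 0.5).
The defaults use $\lambda = 0.1$.

Two deliberate numerical choices:

* **Growth update.** Densities update multiplicatively,
  $S \leftarrow S e^{r\,\Delta\tau}$, rather than by forward Euler. This
  guarantees nonnegativity even under the strong transient inhibition the
  linear inhibitory response can produce (rates of order $-10^2$/hr when an
  inhibitor accumulates far above $k_{sat}$); at `dtau` = 0.01 hr and
  moderate rates the two updates agree to $O(\Delta\tau^2)$.
* **Consumption bookkeeping.** The mediator equation as written removes
  $\alpha_{ji} S_i$ regardless of how much mediator is left, which can push
  $C_j$ negative. The default keeps that form and clamps $C_j$ at zero after
  each growth/uptake step. A `consumption_saturating = TRUE` mode instead
  multiplies consumption by $C_j/(C_j + k_{sat})$ so uptake vanishes as the
  pool empties; it is provided for users who prefer a strictly
  positive-stock interpretation, and is off by default. Production and
  consumption stay on even where a species' net growth rate is negative.

The well-mixed counterpart is the identical kernel on a single grid point
with diffusion disabled — same `dtau` stepping, same clamping — so
spatial-vs-well-mixed comparisons differ only through space. The
*infinite-dispersal* mode runs the spatial grid but re-uniformizes every
species field after each growth step (and starts uniform); with uniform
fields the diffusion operators are exact no-ops, so this mode reproduces
the well-mixed trajectory and serves as an internal consistency check.

Tests cross-check the compiled kernel three ways: against closed forms
(exponential growth, cosine eigenmode decay $e^{-D(\pi/Z)^2 t}$, mass
conservation), against a plain-R reference implementation of the growth
step, and against a `deSolve::lsoda` integration of the continuum ODE in
the well-mixed limit (2% tolerance at `dtau` = 0.01 hr, tightening as
`dtau` shrinks, consistent with the $O(\Delta\tau)$ splitting error).

## Enrichment protocol and coexistence scoring

A simulation starts from adjacent, non-overlapping species blocks at low
density: species $i$ occupies its own block of the grid at a local density
chosen so every species has spatial average `TID`$/N_c$ (total $10^4$
cells/ml). Growth proceeds until the spatially averaged total density
reaches `DilTh` $= 10^7$ cells/ml, then everything is divided by
`DilTh/TID` $= 10^3$, preserving the spatial distribution. Each round
contributes $\log_2$(fold growth) ≈ 9.97 generations, so 100 generations
take 11 rounds. Species whose spatial average falls below `ExtTh` = 0.1
cells/ml at a transfer are zeroed.

Richness counts *stably present* species: present at the end (above
`ExtTh`) and with a relative frequency that declined by no more than 10%
of its value over the last 20 generations (reference point: the latest
round boundary at least 20 generations before the end). A presence-only
variant counts everything above threshold. Shannon diversity
$H = -\sum p_i \ln p_i$ is computed over final relative abundances.

Decisions where the protocol is underdetermined, fixed once and exposed as
configuration:

* the dilution trigger is the spatial *average* of total density (the
  dimensionally consistent match to the well-mixed trigger), not the local
  maximum;
* mediators are diluted by the same factor as cells at transfer (simplest
  rule consistent with a preserved spatial distribution; `retain` and
  `reset` modes are available);
* extinction is evaluated on the spatially averaged density, which is far
  above any discretization artifact and keeps the criterion
  grid-independent;
* a round that never reaches `DilTh` is abandoned at `max_round_hours`
  (2000 hr) with generations computed from the realized fold growth, and
  `max_rounds` (100) bounds the protocol as a whole — with near-zero net
  growth, accumulated generations alone would not terminate.

## Ensembles, sweeps and statistics

`run_ensemble()` simulates many random communities under one condition;
instance $k$ always uses `instance_seed(master_seed, k)`, so conditions
and modes are paired by construction. `sweep_richness()` runs full
factorials over network parameters and configuration fields with these
shared seeds, reporting mean richness per condition with a percentile
bootstrap CI (100 resamples of the mean, order-statistic quantiles). The
pairing is a design choice to sharpen trend comparisons at moderate
ensemble sizes; the trends themselves do not depend on it.
`shuffle_experiment()` re-runs one fixed network under random permutations
of the initial block order to quantify how much coexistence depends on who
starts next to whom.

## Problem sizes

The acceptance-level checks in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` run the full default habitat (100 grid points, 100
generations, 11 rounds) with ensemble sizes chosen to keep a complete run
in the tens of minutes on one core: 30 paired instances per fac:inh
condition, 20 for the dispersal, mediator-diffusion and carrying-capacity
contrasts and the infinite-dispersal pairing, and 5 networks × 5 shuffles
per arm of the arrangement-shuffling comparison. These sizes resolve the
direction of each trend (the package asserts directions, not absolute
figure values); per-condition means stabilize further at the hundreds of
instances a dedicated study would use, which remain available through
`n_instances`. Two contrasts deserve a caveat: the paired
spatial-vs-well-mixed richness gap under prevalent facilitation and the
decline from low to intermediate cell dispersal both have small mean
effect sizes in this implementation (a fraction of one richness unit,
against a per-instance spread of about 1.4), so their sign is only weakly
resolved at these ensemble sizes and ensembles of several hundred
instances are recommended before leaning on either effect.

## What the generator does and does not emulate

The random ensembles emulate chemically mediated interaction structure:
binomial link placement, uniform rate variation within a fixed range, a
dialled facilitation:inhibition balance, and uniform dispersal/diffusion
across species and mediators. They do not emulate degree-correlated or
empirically calibrated topologies, correlations between production and
consumption, nonlinear or context-dependent mediator effects, demographic
stochasticity, or heterogeneous movement rates — so passing trend tests
says the *mechanism* behaves as described under these idealized ensembles,
not that any particular real community will show the same effect sizes.

## Known limitations

* 1D habitat only; no advection; deterministic dynamics.
* The linear inhibitory response is unbounded in $C$, so strongly
  inhibitory communities can experience very fast die-offs; this is the
  model as specified, not a numerical artifact (the multiplicative update
  keeps it well-behaved).
* Event interleaving introduces $O(\text{sub-step})$ ordering error;
  halving `dz` (and hence quartering `dt`) changes final abundances by
  under 2% in the reference scenario covered by the test suite.
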