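---
title: "An individual-based model of lytic phage attack on biofilms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of lytic phage attack on biofilms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagefilm)
```

## The model

`phagefilm` simulates the population dynamics of a surface-attached
bacterial community under attack by a lytic bacteriophage. Two strains —
a phage-susceptible wild type and a phage-resistant mutant paying a
growth-rate cost `c` — are tracked as discrete cells on a lattice of
3 µm nodes above a solid substratum, with periodic lateral boundaries
and an open top. Virions are tracked individually as well: they move by
an impeded lattice random walk, adsorb to biomass, infect susceptible
hosts, and burst after a latent period. The parameterization follows
experimentally constrained values for *E. coli* and phage T7.

Each iteration (`dt` = 7.5 min by default) executes nine stages in a
fixed order:

1. nutrient diffusion (quasi-steady reaction–diffusion solve),
2. biomass growth and division,
3. lysis of infected bacteria and phage burst,
4. erosion of biomass,
5. phage movement,
6. detachment of disconnected biomass,
7. phage infection,
8. biofilm shoving relaxation,
9. advective removal of off-biofilm phages.

The phage life-cycle stages are ordered by the lytic cycle
(burst → disperse → infect), and the biofilm stages by the sequence
nutrient uptake → growth → loss; shoving closes the cycle.

## Nutrients and growth

A single growth-limiting substrate diffuses from a well-mixed bulk
layer that sits a boundary-layer height `h` = 15 µm above the highest
point of the biofilm front. Because the substrate diffusivity
(`D_N` = 2.3×10⁻⁶ cm² s⁻¹) equilibrates concentrations over the
150 µm domain in seconds — far below `dt` — the field is solved to
quasi-steady state every iteration:

`D_N ∇²N = q_max · B_eff/dV · N/(K_N + N)`

with `N = N_max` on all nodes at or above (front maximum + `h`),
no flux at the substratum, and periodic sides. `B_eff` is the
cost-weighted mass of actively consuming cells, so that consumption
equals growth divided by the yield `Y` exactly; infected and
growth-halted cells neither grow nor consume (their only role is to
lyse after the latent period). The Monod nonlinearity is resolved by
Picard iteration of sparse direct solves to a relative tolerance of
10⁻⁶ (cap 10⁴ iterations; the cap is an error, not a silent stop).
The discretization is node-centred; the no-flux condition is imposed by
dropping the substratum neighbour term, which places the reflecting
plane exactly at the wall, and the bulk condition enters through the
Dirichlet neighbour row. For a parabolic (zero-order-limit) profile this
discretization is exact at node centres, which is what the
constant-sink acceptance check exploits.

Cells grow as `dm = (1 − c) · µ_s · N/(K_N + N) · m · dt` and divide
symmetrically at `2·m_s` (mass per cell `m_s` = 10⁻¹² g), conserving
mass exactly. The maximum growth rate is not a free parameter: it is
derived from the substrate uptake rate and yield as `µ_s = q_max · Y`
(28.5 × 0.495 ≈ 14.1 day⁻¹), and a configuration supplying an
inconsistent explicit `µ_s` is rejected at load time.

## Biomass mechanics

**Shoving.** No node may exceed the packing capacity
`S_max · dV` = 5.4×10⁻¹² g. Over-capacity nodes move one randomly
chosen whole cell to their least-full lattice neighbour. Deep inside a
slab of nodes all at capacity that local rule alone livelocks — the
least-full neighbour is always the hole the cell just left — so when no
neighbour has room the excess is resolved by a displacement chain: one
cell per hop is passed along the shortest path (breadth-first search)
to the nearest node with spare capacity. Every cell still moves at most
one node per push, which keeps lineage sectors spatially coherent, and
each chain strictly reduces the total excess, so the relaxation
provably terminates.

**Erosion.** Fluid flow is implicit. Front cells (occupied nodes with
an empty neighbour toward the liquid — above or lateral) are removed
with probability `min(1, δ_E y² dt/dl)`, the height-dependent front
speed `δ_E y²` (erosion constant `δ_E` = 20 (m·h)⁻¹) converted to a
per-node hazard; `y` is the node-centre height.

**Detachment.** Connected components of biomass (von Neumann adjacency,
periodic laterally) that do not touch the substratum are removed
entirely each iteration.

## Phage transport and infection

Each virion receives `n = round(D_P dt / (2 dl²))` potential steps per
iteration (955 at the default T7 diffusivity), each of duration
`dtp = 2 dl²/D_P` ≈ 0.47 s. Per step:

1. If the virion is off the biofilm, it is removed by advection with
   probability `1 − exp(−dtp · d² · δ_P)`, where `d` is the Euclidean
   distance to the nearest biomass-containing node (shear grows with
   distance from the surface).
2. A target node is chosen: the virion stays put with probability
   `erf(1/√(2aπ))` — 0.42 in 2D (`a` = 1), 0.22 in 3D (`a` = 4),
   obtained by integrating the Gaussian step kernel over one node — or
   moves to one of the `2·dim` neighbours uniformly. Moves into the
   substratum are spent in place.
3. The virion interacts with biomass with probability
   `1 − exp(−dtp (I_s + I_t))`, where `I_x = Σ (m_i/m_s) I_i / dV` sums
   the interaction-rate parameter over the cells of the source and
   target nodes. The check applies also when the sampled target is the
   current node, since a virion sitting in biomass is in contact with
   it.
4. On interaction the virion ceases motion — permanently. It is now
   adsorbed to the biomass of its node. Otherwise it moves.

Adsorbed virions make a single infection attempt at adsorption: a host
is drawn from the node weighted by `m_i I_i`, and the contact fires with
probability `1 − exp(−γ · dtr)` where `dtr = dt · s / n` and `s` is the
number of steps taken before stopping. A fired contact on an uninfected
susceptible host starts an infection (the virion is consumed; the host
lyses into β = 120 progeny after τ = 28.8 min). A drawn host that is
already infected yields nothing. Resistant hosts respond by mechanism:
`ABORTIVE` (the default, modelling a ΔtrxA-like abortive infection)
kills both host and virion; `PHAGE_NEUTRALIZING` (restriction/CRISPR-like)
consumes the virion and spares the host; `SURFACE` (receptor-loss)
cannot bind the virion at all — it is released and resumes walking next
iteration, optionally halting the host's growth when the
`halt_on_contact` variant is enabled. Virions whose single attempt does
not fire remain bound as inert sorbed particles — the model's
representation of sorptive scavenging — until the biomass of their node
is gone, at which point the end-of-iteration sweep removes them along
with every other virion left in a biomass-free node.

Three conventions in this stage are deliberately configurable because
the choice is scientifically meaningful:

* `dtr_convention`: `"printed"` (`dt·s/n`, default) versus
  `"complement"` (`dt·(n−s)/n`). The printed form makes a virion's
  lifetime infection probability roughly `γ·dt·E[s]/n` ≈ 2%, which is
  the regime in which a 120-virion pulse fails to infect at all in a
  few percent of runs — the situation the replicate-retention rule
  (below) exists to handle — and in which resistant-majority biofilms
  sequester phages without being destroyed by them. The complement form
  makes nearly every adsorption infectious; epidemics then annihilate
  whichever strain is locally in the minority.
* `infection_attempts`: `"once"` (default) versus `"per_iteration"`
  retrying.
* `interaction_normalization`: `"per_node_volume"` (default, the
  `1/dV` normalization above, giving a root-mean-square adsorption
  reach of roughly 17 µm into biomass) versus `"per_cell"` (27×
  stronger, stopping virions within one or two nodes of contact).

## Events, exit, and replicate bookkeeping

Founders of mass `m_s` are placed on the substratum (one per bottom
node by default; fractional densities scatter founders over random
columns), each independently resistant with probability
`resistant_fraction`; a `ratio` assignment mode fixes the inoculum
composition exactly instead. When the global front height reaches the
pulse threshold (30 µm by default; 20 and 50 µm are the tested
variants), phages are introduced either as a 120-virion `POINT` pulse
into the highest node containing susceptible biomass — one bursting
cell's worth — or as a 300-virion `SPRAY` over random columns 9 µm
above the local front. Continuous-exposure scenarios repeat the pulse
for a configured number of consecutive iterations (`Inf` allowed). The
first pulse defines the infection time; runs end at fixation of either
strain, at infection time + `endpoint_days_after_infection` (10 days by
default), or at the hard cap `max_days` (the endpoint for phage-free
control runs).

A replicate record carries the resistant frequency at inoculation, at
the first pulse, and at exit. Frequency change after exposure,
`Δf = f_after − f_before`, is baselined at the pulse by default so that
pre-pulse drift and cost-driven decline do not contaminate the measure
of what the phages did; the inoculation baseline is also available.
Sweeps over nutrient, initial frequency, cost, interaction rate and
removal rate derive replicate seeds injectively from the base seed, and
aggregate only retained replicates: a run is retained when its peak
phage count exceeds 150, i.e. when the 120-virion pulse amplified at
least once. Cells are classified `POSITIVE`/`NEGATIVE`/`NEUTRAL` by the
sign of the mean Δf with a neutrality band ε = 0.02 (unstated in the
source material; exposed as an argument).

## Desk-scale study conditions

The full published-scale experiment — a 900×150 µm domain, 21 nutrient
levels × 21 initial frequencies × ~100 seeded replicates, each run to
infection + 10 days — is configuration-reachable but takes cluster
time. The package's tests use desk-scale conditions chosen once:
a 300×90 µm domain, bulk nutrient 4 mg L⁻¹ (mid-range), interaction
rate 0.09 (m_s µm³)⁻¹ s⁻¹ and removal rate 0.1 (µm² h)⁻¹ (mid-range on
their respective scales), pulse at 20 µm (the published early-pulse
variant), endpoints of 2 days for phage-free controls and 3 days after
infection for pulse experiments, and 10–20 seeds per condition. The
frequency-dependence checks evaluate retained replicates only, exactly
as the sweep machinery does.

What the simulated conditions emulate is the competition of two
otherwise-identical strains in a nutrient-gradient biofilm under a
single localized phage exposure. What they do not emulate: real
inocula are not always binomial single cells per site (the founder
density and assignment mode materially shape lineage-sector widths,
and sector geometry in turn decides how much of a rare strain is
within phage reach of the epidemic); extracellular-matrix gradients,
curli-mediated surface shielding, multi-species architecture and
ongoing resistance mutation are all outside the model, as are
temperate phages. Passing desk-scale tests therefore demonstrates the
mechanics and their calibration, not quantitative prediction for any
particular experimental biofilm.

## Numerical choices and degenerate inputs

* Units are normalized internally to µm, hours, grams and mg L⁻¹; all
  table values are converted at load and the conversions are tested.
* Node coordinates are 0-based; physical positions are node centres at
  `(i + ½)·dl`. `dV = dl³` (27 µm³) including the implicit depth of a
  2D domain.
* The virion walk is executed in compiled code using R's RNG, so runs
  are bit-reproducible from the seed; ties in host selection, shoving
  targets and pulse placement are broken by R-level `sample()` draws.
* Phage y-positions may transiently exceed the domain top by up to
  30 µm of virtual liquid rows; beyond the cap a step is spent in
  place. Off-biofilm virions are in any case removed by the
  end-of-iteration sweep, so the cap has no observable effect.
* An empty grid yields an infinite distance-to-biofilm sentinel; with a
  positive removal rate, virions there are removed with probability 1.
* A grid saturated to capacity everywhere leaves shoving excess
  unresolved (flagged internally) rather than looping; domains should
  be tall enough that the biofilm never fills them.
* Zero phage diffusivity yields a zero-step walk and an undefined step
  time (an error for `step_time`, a no-op walk in the engine).

## Known limitations

The dynamic engine is two-dimensional; the lattice geometry, stay
probability and walk kernel support three dimensions (the 3D stay
fraction and free-walk statistics are tested), but the nutrient solver
and biomass mechanics are implemented for 2D cross-sections, matching
the scale of the headline analyses. The abortive-infection arithmetic
couples phage pressure to host mortality one-to-one, which makes
outcomes for a *rare* resistant strain acutely sensitive to the
epidemic's total fire count and to lineage-sector geometry — far more
so than the common-resistant side, whose protection rests on the
robust sorptive-scavenging mechanism. Users probing rare-strain
invasion should treat founder density, inoculum assignment and the
three phage-convention switches as first-class experimental factors.

## A worked example

```{r example, eval = FALSE}
library(phagefilm)

cfg <- sim_config(
  space = list(x_max_um = 300, y_max_um = 90),
  sim = list(seed = 14, resistant_fraction = 0.9, max_days = 10,
             endpoint_days_after_infection = 3),
  pulse = list(height_threshold_um = 20)
)
sim <- run_simulation(cfg)
glance(sim)      # one-row outcome record
tidy(sim)        # per-iteration population and event ledger
autoplot(sim)    # populations over time

spec <- sweep_spec(nutrient_values = c(2, 4, 8),
                   initial_frequencies = c(0.1, 0.5, 0.9),
                   replicates = 5, base_seed = 1)
sw <- run_sweep(spec, cfg)
classify_selection(glance(sw))
autoplot(sw)
```
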