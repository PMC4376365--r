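---
title: "Spatially resolved dynamic FBA of bacterial colonies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially resolved dynamic FBA of bacterial colonies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyFBA)
```

## The model

colonyFBA simulates the growth of a dense bacterial colony on a nutrient
agar plate by coupling two descriptions that live on the same cubic
lattice:

* a **reaction-diffusion layer** for the tracked chemical species
  (glucose, oxygen, acetate by default), and
* a **constraint-based metabolic layer** that predicts, per lattice site,
  how fast the local cells grow and what they exchange with their
  surroundings, by flux balance analysis (FBA) of a stoichiometric model.

Every site is air, agar, or cell-occupied. The cells at a site are not
resolved individually; a site carries a *volume fraction* $\rho_i$ of
each regulatory state $i$, continuous up to a packing limit
$\rho_\max = 0.65$ (roughly 650 rod-shaped cells per $10\,\mu m$ site).

### Diffusion

Substrates move by a seven-point-stencil explicit finite-difference
scheme. The flux across the face between sites $i$ and $j$ uses the
arithmetic mean of the two sites' diffusivities,

$$J_{j\to i} = \frac{D_j + D_i}{2}\,\frac{\phi_j - \phi_i}{\lambda},$$

which keeps fluxes continuous across agar/cell interfaces. Updates are
Jacobi (simultaneous), so results never depend on traversal order.
Diffusivities are the literature water/agar values; substrates that
cannot cross the cell membrane (glucose and acetate here) must diffuse
*around* cells, with the hindered coefficient

$$D_{\mathrm{eff}} = D\,\frac{1-\rho}{1+\rho/2}.$$

Air sites act as sources: they are clamped to each substrate's air value
(oxygen: $260\,\mu M$, from Henry's law at $p_{O_2} = 0.2$ atm and
$k_H = 0.0013$ mol L$^{-1}$ atm$^{-1}$), fluxes from air into the domain
are allowed for volatile species, and fluxes from agar or cells into the
air are suppressed so aqueous species cannot escape. Glucose is held at
its plating concentration (2.5 g/L $= 13.9$ mM by default) on the agar
walls and floor; the acetate boundary is held at zero so that every
acetate molecule in the simulation is colony-made.

A note on the time step: the one-dimensional stability bound
$\lambda^2/2D \approx 2\times10^{-2}$ s (for oxygen in water at
$\lambda = 10\,\mu m$) is what `stability_bound()` reports and what
configuration validation enforces. The sharper von Neumann bound for the
three-dimensional seven-point stencil is $\lambda^2/6D \approx
6.4\times10^{-3}$ s; all shipped sub-step defaults (1 ms for full-scale
configurations, 5 ms for the scaled-down scenarios) sit below it, and the
analytic column oracle (below) verifies accuracy at the coarser value.

### Uptake and the FBA kernel

Glucose import is an active, transporter-mediated process and is modeled
with Michaelis-Menten kinetics ($v_{\max} = 10.4$ mmol gDwt$^{-1}$
hr$^{-1}$, $k_m = 0.37$ mM, fit constants); each sub-step moves
$k\,\Delta\tau$ from the shared extracellular pool into an intracellular
pool that travels with cell volume. Oxygen and acetate cross membranes
freely and are consumed directly from the extracellular field, with
kinetic caps of 31.8 and 16.0 mmol gDwt$^{-1}$ hr$^{-1}$ on the exchange
constraint.

During one sub-step the cells of a site can access only the substrate
within their own volume. That availability, converted to a specific rate
and capped by the kinetic limit, bounds the corresponding exchange flux
of the FBA problem. The linear program maximizes the biomass objective
subject to steady state and these bounds; a parsimonious second stage
then minimizes total absolute flux at the fixed optimum, because
otherwise the acetate exchange at optimal growth is degenerate and
tables would not be reproducible. An optional molecular-crowding
constraint $\sum_r a_r |v_r| \le 1$ can be imposed throughout (split
fluxes keep it linear); it reproduces overflow metabolism at high growth
rates when respiration's crowding cost exceeds overflow's.

Solving an LP per cell site per millisecond is hopeless, so solutions
are **precomputed on a rectangular grid** over the availability space
(one grid per regulatory state, linear axes from zero to each kinetic
cap) and served by multilinear interpolation, with every interpolated
uptake clamped to the queried availability so no site is ever
overdrawn. Node queries are exact by construction; between nodes the toy
model's worst-case growth-rate error at 9 nodes per axis is a few
hundredths of an hr$^{-1}$ and at least halves with each grid doubling,
which is why 9 nodes suffice for the scaled-down scenarios (the default
is 17).

Because no LP backend is available to R in this environment, the package
carries its own dense two-phase simplex with Bland's anti-cycling rule.
It is deliberately simple and deterministic; it limits model size to
desk scale (tens of reactions), which is also the scale at which every
test oracle (exhaustive vertex enumeration) can operate.

### Time-scale separation, growth, expansion

Substrate profiles relax within seconds while the colony shape changes
over minutes, so the simulation alternates a short relaxation window
($t_{ss} = 1$ s of sub-steps) with a colony update every $t_{grow} = 60$
s. Each colony update applies, in order:

1. **Growth**: $\rho_i \leftarrow \rho_i e^{g_i t_{grow}}$, with each
   state's own table-reported growth rate (co-resident states share
   substrate availability but metabolize differently).
2. **Expansion**: sites above $\rho_\max$ push volume through their
   faces, $\rho_{i\to j} = \tfrac{1}{12}[\max(0,\rho_i-\rho_\max) -
   \max(0,\rho_j-\rho_\max)]$, iterated (Jacobi) until the worst
   over-filling is within $\Delta\rho = 0.01$. The $\tfrac1{12} =
   \tfrac12\cdot\tfrac16$ spreads over six faces with a factor-two
   damping that guarantees monotone convergence. Volume may displace air
   (colonizing new sites) but never agar, so colonies grow up and
   outward. State composition and intracellular pools travel with the
   moved volume in donor proportions.
3. **Regulation**: first-order switching between states at rates given
   by clamped quadratic polynomials of two local concentrations,
   explicit-Euler at the $t_{grow}$ cadence, with outflows capped at the
   available volume so per-site totals are conserved exactly.
4. **Summary**, taken here -- on the converged fields -- because step 5
   intentionally distorts local pools.
5. **Projection**: the agar reservoir drains slowly; the net per-site
   *drawdown* recorded over the final sub-step is extrapolated across
   the remaining $t_{grow} - t_{ss}$ seconds and floored at zero.
   Only the negative component is extrapolated: projecting a field still
   rising toward its quasi-steady value overshoots and can feed a
   growing inter-cycle oscillation (observed during development),
   whereas leaving sources to the relaxation windows is conservative and
   cannot create mass.

### Regulation and the batch acetate switch

The default two states are glucose consumers (acetate uptake forbidden)
and acetate consumers (glucose uptake forbidden). Their interconversion
rates are calibrated against batch-culture data through a well-mixed
two-state growth model: exponential growth of each state on its own
substrate, glucose consumption and acetate production by the glucose
state, acetate consumption by the acetate state, and the polynomial
switching terms. Calibration is staged: growth rates from log-linear
fits of the single-substrate biomass curves; consumption/production
rates from the same cultures' substrate curves (closed-form least
squares, since each is linear in the unknown rate given exponential
biomass); switching coefficients from the mixed culture by
Levenberg-Marquardt trajectory fitting, seeded with a gradient-matching
(derivative regression) estimate.

Not every polynomial term is identifiable from batch *down-shift* data.
The forward switch is fully suppressed while glucose is plentiful (its
clamped rate is zero through the whole glucose phase), so its glucose
coefficient acts only in a sub-millimolar window too brief to resolve;
the back-switch's concentration terms would require a glucose up-shift
experiment. The calibration template therefore fixes those terms and
fits the remaining four; the shipped defaults are calibrated against
this package's own synthetic generator and are clearly *not* literature
values -- user coefficient files are accepted everywhere.

## What the synthetic data emulate -- and what they do not

The generator produces the three canonical culture conditions
(glucose-only, acetate-only, mixed) on realistic grids with unbiased
multiplicative log-normal noise, emulating optical-density plus
substrate-assay series. It shares the integrator with the calibration's
forward model, so noiseless round trips are exact by construction; they
demonstrate correctness of the staged estimator, not robustness to model
misspecification (real cells show a switching lag that neither the
model nor the generator contains).

The toy metabolic network (8 reactions, 5 metabolites) encodes exactly
the qualitative physiology the colony scenarios need -- high-yield
aerobic respiration (3 O$_2$ per glucose), low-yield anaerobic overflow
to acetate, intermediate-yield aerobic acetate oxidation, with yields
tuned to a 46-minute aerobic doubling time. It stands in for a
genome-scale reconstruction at desk scale; passing tests show the
spatial method is correct, not that any particular organism's flux
distribution is.

## Scaled-down study conditions

The emergence scenarios run on a $64\times64\times48$ lattice
($10\,\mu m$ spacing, 16 agar layers) for 12 simulated hours with a 5 ms
sub-step, seeded with one fully packed site ($\rho = 0.65$, about 650
cells) of glucose-state cells at the center of the agar surface. The
packed-site inoculum -- streaked plates deposit clumps, and the seed
count is experimentally uncertain anyway -- brings the two regimes of
interest inside the 12-hour horizon: an anoxic core (oxygen below 1% of
its air value) with acetate-secreting cells confined to the glucose-rich
bottom of the interior, an acetate-consuming shell in the oxygenated
region above, and a late linear radial-expansion phase carried by the
ring of well-fed "pioneer" cells at the edge. At this scale the oxygen
penetration depth at the agar surface comes out at $\sim$40 $\mu m$ and
the glucose penetration height at the colony axis at $\sim$50 $\mu m$,
with roughly a third of secreted acetate re-consumed and a measurable
whole-colony growth advantage over a variant forbidden from taking
acetate up. The corresponding full-scale configuration (the package
default: $320\times320\times192$, 48 h, 1 ms sub-steps, a genome-scale
SBML model) uses the same code paths but needs a cluster and an external
model file, and is therefore not part of the test suite.

## Numerical choices and degenerate inputs

* Negative concentrations beyond $-10^{-15}$ M abort with a stability
  diagnostic; smaller excursions are floating-point noise and are
  clamped.
* Active import is rate-capped at $\phi_{ext}/\Delta\tau$ per sub-step
  so exhaustion within a sub-step cannot produce negative pools
  (cap events are counted, not silently ignored).
* Newly colonized sites inherit zero aqueous concentration and the air
  value for volatiles -- the conservative choice; diffusion
  re-equilibrates them within the next relaxation window.
* Ties among optimal flux vectors are always broken parsimoniously;
  repeated solves are bit-identical, and the whole trajectory of a run
  is deterministic (no randomness anywhere in the core loop).
* The exponential-to-linear transition of the radius series is located
  by a two-phase changepoint fit (exponential before, linear after,
  minimizing total squared error), accepted only if it beats a single
  linear fit by an AIC margin.
* Relaxation windows are honored as fixed intervals rather than
  adaptively shortened; a convergence diagnostic (max relative field
  change over the last 10% of sub-steps) is reported, not acted on.
  Reproducibility is preferred over speed.

## Limitations

All cells in a site behave identically and optimally; stochastic gene
expression, switching lags, mechanics (EPS, friction, surface tension),
cell death, and evaporation are outside the model. The lookup-table
design requires choosing the tracked substrates up front -- here
glucose, oxygen and acetate, with the fermentation screen
(`fermentation_screen()`) as the tool for making that choice for other
models. The built-in simplex is not suitable for genome-scale models;
point the SBML reader at one only if an external LP backend is wired in
its place.

## A worked micro-example

```{r example, eval = FALSE}
model <- build_toy_model()
states <- acetate_switch_states()
table <- build_flux_table(model, states, axes = default_axes(model, 9))
sc <- scaled_scenario("regulated", dims = c(32L, 32L, 28L),
                      agar_layers = 8L, table = table)
run <- simulate_colony(sc$lattice, sc$table, sc$switching, hours = 6)
tail(run$summaries[, c("time", "radius", "biomass", "production_ace")])
fit_radial_rate(run$summaries)
```
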