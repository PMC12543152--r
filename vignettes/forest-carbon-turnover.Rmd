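---
title: "A desk-scale forest carbon simulator for management effects on turnover time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale forest carbon simulator for management effects on turnover time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(foresttau)
```

## What the package models

`foresttau` is a reduced, annual-step forest carbon simulator built to study
one question: how do stylised forest management options — an 80-year
clear-cut rotation with Reineke-rule thinning and scenario-specific
replanting (keep the current species, convert to needle-leaved evergreen,
broadleaved deciduous, or broadleaved evergreen plantations, or stop
managing altogether) — change the carbon turnover time τ of the ecosystem,
the stem pool and the soil, with and without climate warming?

Carbon turnover time is estimated throughout as a pool/flux ratio over an
averaging window,

τ = mean(C pool) / mean(outflow),

which assumes the pool is near steady state over the window. The package
computes:

* **τ_eco** — ecosystem carbon (live biomass including leaves and fine
  roots, plus all litter and soil pools; the wood product pool is outside
  the ecosystem) over the total ecosystem outflow
  `FRa + FRh + FDOC + Ffire + Fharv_to_products + Fharv_to_atm`.
* **τ_stem** — stem carbon (stem, branches and coarse roots; leaves and
  fine roots excluded as ephemeral) over
  `Fmort + Fdist + Ffire(live stem) + Fharv(stem)`, where the harvest term
  is the whole felled stem flux, including the residue left as litter.
* **τ_soil** — all ten soil/litter pools over total heterotrophic
  respiration; plus per-pool τ for the surface coarse and fine woody
  debris, surface humus and slow SOM pools, each using the pool's *total*
  outflow (respiration + transfers + leaching).
* **τ_gpp** — ecosystem carbon over GPP, the flux *entering* the
  ecosystem. At steady state τ_gpp = τ_eco exactly; in an accumulating
  forest τ_gpp < τ_eco, so the pair is a built-in equilibrium diagnostic.

Everything runs on synthetic forcing, so the full experiment design —
spin-up, historical age-structure initialisation, five management
scenarios, two climate modes, zone and dominance aggregation — is testable
end to end on a desk.

## Model structure

### Vegetation

A grid cell holds one stand of 25 patches (the replicate sub-units over
which stochastic disturbance averages). A patch holds cohorts of four
plant functional types: needle-leaved evergreen (NE), needle-leaved
deciduous (ND), broadleaved deciduous (BD), broadleaved evergreen (BE).
A cohort carries age, stem density, and carbon in stem (including branches
and coarse roots), leaf and fine root.

Annual production is deliberately simple: GPP is a saturating function of
the patch's total leaf carbon (shared canopy; cohorts split the captured
light by leaf share), modulated by a Gaussian temperature response around a
PFT optimum, a saturating moisture factor, the radiation index, and a
logarithmic CO2 multiplier (β = 0.5 per unit log CO2; β = 0 disables
fertilisation). Autotrophic respiration is Q10 = 2 maintenance on all live
pools plus a 25% growth-respiration share, capped at GPP so NPP is never
negative. Deciduous tissues get lower maintenance coefficients than
evergreen ones (the canopy only lives half the year), which gives
broadleaved deciduous stands their higher carbon-use efficiency.

Allocation is demand-first: NPP first replaces the year's leaf and
fine-root turnover (leaf longevity 1 yr for deciduous, 2–4 yr for
evergreens; fine roots 1 yr), and only the surplus is allocated to growth
by fixed PFT fractions. Leaf and fine-root pools saturate at PFT maxima
(canopy closure); beyond the cap their share diverts to stem. This
construction gives an undisturbed cohort an interior fixed point — with all
mortality disabled, live carbon is nondecreasing and converges — which a
fixed-fraction allocation scheme does not have.

Mortality has three channels: a background rate rising with relative age
(`m0 + 0.3 (age/longevity)^5`), growth-efficiency stress when NPP per unit
leaf carbon falls below 0.2 yr⁻¹, and a bioclimatic kill that removes a
whole cohort when the (smoothed) coldest-month temperature or growing
degree days leave the PFT envelope. Kills are binomial draws over the
patch's stems (patch area 1000 m²); a deterministic expected-fraction mode
exists for designed experiments. Stochastic patch-destroying disturbance
hits each patch independently with probability 1/400 yr⁻¹. Fire is a
deterministic parametric flux on unmanaged patches only (managed stands
burn nothing, exactly): an annual burned fraction (base rate 0.004 ×
dryness multiplier) combusts fixed fractions of leaf, stem and surface
litter carbon; killed-but-uncombusted biomass becomes litter.

Height follows a power-law allometry of per-stem stem mass
(`h = 5 m^(1/3)`), and diameter the inverse of `m = 0.06 D^2.5`. Cells
whose scenario-average height over the τ window is below 5 m do not count
as forest and are excluded from comparisons (closed lower bound: exactly
5 m is retained).

### Management

Managed stands follow a synchronised clear-cut rotation (default 80 years,
60 and 100 supported), with the first clear-cut at the management start.
Between clear-cuts, thinning is triggered by Reineke's rule:
`N_max = SDI × (D_q/25 cm)^(-1.605)` with SDI 1100 stems ha⁻¹ for
needle-leaved and 700 for broadleaved groups, so broadleaves thin at lower
densities; stands above `N_max` are thinned to 90% of it, proportionally
across cohorts. All felled biomass — clear-cut or thinning — follows one
harvest pathway: 66% of wood and 30% of leaf biomass are removed (the rest
is litter; fine roots all become litter); all removed leaf and 67% of
removed wood oxidise the same year; the remaining 33% of removed wood
enters a product pool that oxidises at 4% yr⁻¹ (oxidised *before* the
year's input is added — the ordering matters only in the 4th decimal).
For τ_eco, the ecosystem outflow is the export to the product pool at
harvest time, not the pool's later oxidation.

Replanting: the baseline replants the pre-death composition; the
transition options replant only their target PFT; unmanaged stands
regenerate naturally with whatever PFTs the local climate admits. The lag
is one year, except after a clear-cut (same year).

The initial age structure emulates 140 years of progressive conversion:
starting from an all-pristine stand, clear-cut waves every 10 years convert
patches so that the managed age histogram at the management start matches a
target distribution (default: uniform over 0–140 years plus a 12%
">140-year" tail that stays pristine), apportioned to the 25 patches by
largest remainder — one patch is the quantum of area. Ledger fluxes and
all τ values describe the converted ("managed-fraction") patches; the
pristine patches keep burning and regenerating and the whole-stand totals
are recorded alongside (`*_all` columns) so mass conservation can be
checked over the entire stand every year.

### Soil

Litter and soil organic matter follow a ten-pool CENTURY-style cascade:
surface coarse and fine woody debris (dead stem wood, split 70/30), surface
structural/metabolic litter (leaves, split by a PFT metabolic fraction),
soil structural/metabolic litter (fine roots), and surface humus, active,
slow and passive SOM. Each pool decays by the linear annual fraction
`min(1, k · f(T) · g(P))` with Q10 = 2 temperature and saturating moisture
modifiers; decayed carbon splits into a respired share (≈55–60%), transfers
along an explicit topology matrix (woody debris and surface litter feed
surface humus and the active pool; soil litter feeds active and slow;
active ↔ slow exchange with small leaks to passive), and DOC leaching from
the active pool (coefficient 0.01 × moisture factor). The rate constants
(k from 7 yr⁻¹ for metabolic litter down to 0.002 yr⁻¹ for passive SOM)
keep the documented per-pool τ ordering: passive > slow > surface humus >
coarse woody debris > fine woody debris > metabolic. Because the topology
and fractions live in one config block, alternative cascade readings are
config edits, not code edits.

The whole cascade is linear, so its equilibrium for a constant input is a
linear solve (`soil_equilibrium()`). The simulator uses this to accelerate
spin-up: at the end of the vegetation spin-up phase the soil vector is set
to the analytic equilibrium of the mean litter input over the last 50
spin-up years. This is the one simulated year in which the ledger identity
below does not hold (the replacement is flagged by construction and
excluded from the conservation tests); every other year closes exactly.

### Accounting identities

The annual ledger satisfies, to floating-point precision,

ΔC_eco = GPP + F_plant − (FRa + FRh + FDOC + Ffire + Fharv_to_products + Fharv_to_atm)

ΔC_soil = F_litter − FRh − FDOC − Ffire(litter)

where `F_plant` is the small seedling carbon imported at (re)planting
events (0.18 kgC m⁻² per fully planted patch — establishment biomass is
created, not grown, exactly as in cohort-based gap models) and
`Ffire(litter)` the directly combusted surface litter. Both identities are
asserted every year of a 50-cell run in the test suite at 10⁻⁹ relative.

## The synthetic forcing

The grid generator assigns each cell one of five Köppen-style zones
(arid; cold with cold summer; cold with warm summer; temperate without dry
season; temperate with dry summer — tundra is excluded as unforested), a
zone-typical climate archetype (annual mean temperature, seasonal
half-amplitude, precipitation and its summer share, radiation index) with
small jitter, and an initial dominant group (needle-leaved with
zone-specific probability, e.g. 0.9 in cold-with-cold-summer, 0.15 in
arid). Zone assignment from a climate summary uses documented simplified
thresholds (arid when P < 20·T + 280 mm; cold when the coldest month is at
or below −3 °C, warm-summer when ≥4 months exceed 10 °C; dry summer when
the April–September precipitation share is below 0.35), and each cell's
jittered climate is kept consistent with its label.

Forcing is annual — the τ arithmetic is annual, and daily physiology is
out of scope. The fixed mode emulates a detrended, recycled climate: one
20-year anomaly block per cell (zero mean, zero OLS slope) recycled
verbatim, with constant CO2 (400 ppm) and N deposition. The warming mode
adds a linear temperature trend (+0.04 °C yr⁻¹) and a CO2 ramp (400 → 850
ppm, a high-emissions-pathway analogue) from the management start; spin-up
and history run on the fixed base, so the contrast isolates future change.
Interannual noise standard deviations (0.6 °C; 15% relative precipitation;
0.04 radiation) are free parameters of the stand-in — no source states
them — and are set once here. N deposition is carried in the forcing but
the reduced model has no nitrogen cycle; it is plumbing for config
completeness, not a driver.

## Experiment presets and windows

`preset_management_only()` runs three full rotation cycles (240 years)
under fixed forcing; τ is averaged over the last 30 years of the third
cycle, excluding the synchronised clear-cut year (the window is half-open,
ending at the cut). `preset_management_climate()` runs 90 years under
warming and evaluates the last 30 years of the *first* cycle — the
2060–2089 analogue, chosen so the window closes right before the next
clear-cut. In both cases the window catches ages 50–79 after a clear-cut,
when the only harvest flux is thinning; including a clear-cut year would
shorten τ and was deliberately avoided. The unmanaged option uses the same
calendar windows (clear-cuts are synchronised across options, so windows
align).

Desk-scale defaults: 20 cells, spin-up 300 years (the soil accelerator
makes the slow/passive pools reachable; a 1200-year spin-up is the
faithful setting), history 140 years, 25 patches. The acceptance-style
test experiments use 50 cells × 300 years (conservation), 20 cells × 280
years × 10 runs (warming contrast) and single-cell runs of 460–600 years
(paired harvest and equilibrium designs); these sizes were chosen so each
designed experiment isolates one mechanism cleanly.

Zone comparisons average τ across cells within zone after trimming to the
central 99% quantile band — a few cells with tiny outflows otherwise
distort means; the band uses order-statistic (type-1) quantiles so small
groups are never trimmed away, and the coverage is a parameter (set it to
0.98 for the [1%, 99%] reading). Standard errors are across grid cells
(sd/√n), not across years. The longest-τ label per cell is an argmax with
a documented tie order (base, toNE, toBD, toBE, unmanaged) and a tie flag.
Dominance stratification reports paired per-cell deltas against the
baseline by pre-management dominant group, and excludes scenarios whose
retained-cell set shrinks below half of the baseline's (in practice the
broadleaved-evergreen transition, which fails the 5-m height filter
outside warm zones).

## Numerical and design choices

* **One seeded RNG stream per stand**; draw order is fixed (mortality by
  patch, then one disturbance draw per patch; fire and everything else is
  deterministic), so runs are bit-reproducible from (config, seed).
  Per-cell seeds derive from the master seed with fixed multipliers and
  stay below 2³¹.
* **Missing, not infinite**: any τ whose window-mean outflow is zero is
  `NA` and skipped downstream.
* **Half-open windows** `[start, end)` everywhere; the clear-cut year sits
  at `end` and is excluded.
* **Age bins are right-closed** `(10(j−1), 10j]`; the wave at history
  offset `140 − 10j` produces bin `j` exactly.
* **Degenerate inputs**: empty patches are no-ops; empty stands have
  height 0 and are filtered; a cohort pushed below the density floor
  (10⁻⁴ stems m⁻²) dies entirely and its carbon is routed to litter, so
  nothing is silently lost.
* **Coarse roots are "removable"**: the 66% wood removal includes coarse
  roots because the harvest definition groups stem, twigs and coarse
  roots into one wood pool; ecologically odd but followed literally, and
  confined to one constant.
* **Thinning removals follow the same 66/30 partitioning as clear-cuts**
  (a single harvest pathway); no source distinguishes them.

## What passing tests do and do not show

The synthetic generator emulates zone-typical mean climates, recycled
interannual anomalies, a plausible initial age structure, and the
management machinery itself. It does not emulate real weather sequences,
drought extremes, species mixtures beyond four PFTs, nitrogen limitation,
or disturbance regimes that respond to climate or species composition. So
green tests certify the *accounting* (exact conservation, the printed
harvest constants, the disturbance calibration, rotation arithmetic), the
*identities* (steady-state τ equalities, closed-form pool τ), and the
*directions* of the management and warming contrasts on this synthetic
world — not continental τ magnitudes, which depend on a full
physiological model and real forcing.

Reproduced qualitative patterns include: unmanaged stands have the longest
τ_eco; the broadleaved-evergreen transition fails the forest height filter
outside warm zones; broadleaves thin at lower densities and show short
τ_stem; harvest shortens τ_stem on paired runs; warming shortens τ_eco and
τ_soil under every option. Known divergences of the reduced model: the
broadleaved-deciduous transition does not exceed the baseline's τ_eco here
— its thinning removals outweigh the carbon-use-efficiency advantage at
these parameter settings — and unmanaged τ_soil is not consistently
shorter than managed, because the labile-substrate stimulation of
decomposition by coarse woody debris is not represented. Both belong to
the physiology that is out of scope, and both are stated here rather than
tuned away.

## A minimal session

```{r example}
cfg <- preset_management_only(n_cells = 10, spinup_years = 100, seed = 1)
exp1 <- run_experiment(cfg)
head(exp1$tau)                      # per cell x scenario x pool-kind
exp1$summary                        # zone means with SE, trimmed
longest_tau_map(exp1$tau, exclude_unmanaged = TRUE)
mask <- common_cell_mask(exp1$tau)
dominance_stratify(exp1$tau, mask)  # deltas vs baseline by dominant group
```
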