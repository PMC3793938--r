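---
title: "Simulating grass growth and exploring functional-trait adaptive landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating grass growth and exploring functional-trait adaptive landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasscape)
library(tibble)
options(grasscape.quiet = TRUE)
```

## The question the package addresses

Plant functional traits do not vary freely in nature: specific leaf area
(SLA) and leaf lifespan (LLS) co-vary negatively along the leaf
economics spectrum, and plant height (H) and tiller density (TD) co-vary
negatively along the stature/allometry spectrum.  Observational data
cannot say *why* those particular combinations are occupied.  grasscape
takes the simulation route: it grows a virtual grass plant whose
physiology and morphogenesis are mechanistically coupled, then
deliberately breaks the trait correlations by sweeping a full factorial
grid over the four traits and measuring the performance consequence of
every combination.  Adaptive peaks, ridges and their slopes are then
read off the resulting landscape.

## The simulator

### State and scale

The model follows one *average axis* (tiller) with a daily time step.
State variables are the two labile substrate pools `wc` and `wn` (gC and
gN per axis — the in-planta markers of C–N coordination), two reserve
pools, three structural compartments (shoot structure, represented
explicitly by leaf cohorts; fine roots; photosynthetic protein), the
tiller density `td` (axes m^-2), the two allocation coefficients `p`
(root vs shoot) and `q` (protein vs shoot structure), and the soil
mineral N pool.  Genet-level ("per plant") quantities are obtained by
scaling per-axis fluxes with `td / plant_density`; `plant_density`
(genets m^-2) is a fixed convention, not a dynamic variable.

Axis demography clones or removes *average* axes, so the per-axis C and
N ledgers close exactly under tillering and self-thinning; this is the
only convention under which demography does not create or destroy
untracked mass in an average-individual model.

### Daily process order

1. management events (cutting to a residual height; fertilisation),
2. Beer–Lambert light interception over the sward LAI,
3. gross photosynthesis: a smooth minimum (non-rectangular hyperbola,
   curvature `theta_colim`) of a light-limited limb
   (`eps_light * PAR intercepted`) and a protein-bound capacity limb
   (`amax_protein * w_protein`), down-regulated by a steep product
   feedback when the C substrate saturates relative to structural mass,
4. Michaelis–Menten root N uptake per root area, capped at the per-axis
   share of the soil pool and down-regulated by the analogous N
   feedback,
5. reserve storage (a fixed fraction of the substrate excess over the
   target C:N goes to reserves each day) and linear reserve
   remobilisation; exudation disposes of part of the remaining excess,
6. growth: bilinear (two-substrate) control
   `G = g_max * dTT * W * wc/(wc + kc W) * wn/(wn + kn W)`, split by
   `p` and `q`, capped by the morphogenetic sinks (lamina extension
   capacity of the expanding cohorts; maximum root system size), then
   scaled so the stoichiometric C and N costs never exceed the pools,
7. the substrate mass balance (the two signed flux sums), with any
   residual sink overdraft resolved by a common down-scaling factor so
   pools land exactly at zero,
8. allocation relaxation: `p` relaxes towards
   `p_ref * (C:N)/(C:N target)` (functional balance — N-short plants
   root harder), `q` multiplicatively towards photosynthetic
   co-limitation (light-limited and capacity-limited rates equal),
9. leaf cohort demography in thermal time (new cohort per phyllochron,
   extension towards the potential lamina length, senescence at the
   leaf lifespan with a fixed fraction of tissue N remobilised),
10. logistic tiller dynamics with self-thinning above a critical LAI,
11. the soil mineral N balance (fertiliser, background mineralisation,
    uptake by the stand, first-order leaching loss).

The compiled core (`src/sim_core.cpp`) mirrors this sequence operation
for operation; the reference R implementation (`step_day()` composing
the exported process functions) is retained, and a test holds the two
engines to bit-level agreement over a month and 1e-6 over years (beyond
that horizon, sub-ulp rounding noise is amplified chaotically by the
cutting events).

### Trait mappings

The four manipulated traits enter as parameters:
`ldmc = 1/(SLA * leaf_thickness)` at unit fresh-tissue density and
constant lamina thickness; `l0 = H / height_shape` with a
density-dependent erectness factor `(td/td0)^0.1`;
`phyllochron = LLS / n_leaves_alive` with a constant number of live
leaves per tiller (three), so leaf lifespan and phyllochron stay
proportional; and TD is simply the initial value of the tiller-density
state variable.  Axis demography is deliberately slow
(`tiller_app_rate` 3e-4 d^-1) so the initial density remains
informative over multi-year runs; its long-run creep towards the
self-thinning ceiling is the reason campaigns use a fixed spin-up
length rather than demanding strict convergence.

### Parameters that matter most

| parameter | default | units | role |
|---|---|---|---|
| `eps_light` | 0.68 | gC MJ^-1 | light-limited conversion; sets the C supply side of co-limitation |
| `amax_protein` | 1.0 | gC gProt^-1 d^-1 | capacity limb per protein mass |
| `k_ext` | 0.8 | — | canopy extinction; controls how fast interception saturates with LAI (the crowding penalty) |
| `umax`, `km`, `sra` | 0.3, 0.5, 0.1 | — | N uptake kinetics and root area |
| `g_max`, `kc`, `kn` | 0.012, 0.05, 0.004 | — | bilinear substrate control of growth |
| `cn_target` | 5 | gC gN^-1 | target substrate C:N for functional balance, storage and exudation |
| `lai_crit` | 5 | — | self-thinning threshold |
| `r_maint`, `y_growth` | 0.008, 0.75 | — | respiration costs |
| `plant_density` | 400 | genets m^-2 | per-axis to per-plant scaling |

The defaults were calibrated once so that, for a mid-panel species under
the high-N regime, the observed trait point sits near the C–N–sink
co-limitation point: there, cheapening leaves further runs into
morphogenetic sink limitation (the high-SLA penalty), densifying tissue
runs into C limitation (the low-SLA penalty), and adding axes or
stature runs into interception saturation plus respiration and turnover
costs.  That co-limitation structure — not any individual parameter
value — is what produces interior performance peaks and the ridge sign
pattern.

### Numerical choices and degenerate inputs

* Thermal time accumulates above 0 °C; all morphogenesis is clocked in
  degree-days.  Maintenance respiration follows a Q10 of 2.
* Pools can never go negative: sink fluxes are scaled by the common
  factor that lands the pool exactly at zero, keeping the balance
  equations exact; the C:N ratio is evaluated with the N pool floored
  at 1e-9 gN so it stays defined.
* Tiller density is floored at 10 axes m^-2.
* All argmax operations on grids break ties towards the lower grid
  index; this is deterministic and documented wherever it applies.
* The simulator is fully deterministic; every source of randomness
  lives in the synthetic-data generators and is a pure function of
  `(configuration, seed)`.
* A run aborts with a structured error (class `grasscape_sim_error`,
  carrying the day index) on non-finite state; campaigns record such
  rows with `status = "failed"` and continue.

### Equilibrium, and what "quasi" means here

Under cyclic drivers the fast physiological state (pools, cohorts,
protein, roots) settles within a few annual cycles, which is what the
spin-up is for (campaigns default to three cycles, mirroring the
fixed-length spin-up practice of large virtual experiments).  Two slow
processes keep the *exact* annual map from having a fixed point in
general: axis demography creeps towards the self-thinning ceiling (by
design, to preserve the TD trait signal), and the leaf cohort cycle is
generally incommensurate with the annual thermal time, so end-of-year
snapshots rotate in cohort phase.  `spin_up()` therefore compares
year-mean states, and the test suite demonstrates a true fixed point in
the configuration where one exists (frozen demography, constant
temperature, phyllochron dividing the annual thermal time).  At that
fixed point photosynthetic co-limitation holds in temporal mean (the
stationarity of `q` forces the mean log ratio of the two limbs to
zero); instantaneously the ratio oscillates with discrete cohort
turnover.

## The virtual experiment

`build_trait_grid()` produces ten equidistant values spanning ±30%
around the observed trait value plus the observed value itself (eleven
values unless coincident); four traits, twelve species and two N levels
enumerate to 351 384 runs.  That full design is cluster-scale; the
package's campaigns run the identical code path on reduced grids.
Problem sizes used by the packaged checks: reliability on 5 values per
trait x 2 synthetic archetypes x 2 N levels x 2 scored years (2 500
runs); ridge and unimodality structure on 2-D and 1-D slices (5 values
per trait) for three reference species; plasticity on full 4-D grids
with 3 values per trait at both N levels.  These sizes keep the whole
suite within a coffee break on one core while exercising every stage at
the same resolution per dimension as the full design.

Fertilisation splits the annual total (120 or 360 kgN ha^-1 yr^-1, i.e.
12 or 36 gN m^-2 yr^-1) into four equal applications; three cuts per
year to a 5 cm residual.  The exact field calendar is not public, so
the default days (fertiliser on days 75/135/195/255, cuts on
150/210/270) are declared package conventions.

The two calibration routines mirror field-parameterisation practice:
fine-root maximum length and lifespan are optimised by maximising
equilibrium per-axis structural biomass, and the two axis-demography
rates by fitting the equilibrium tiller density to an observed value —
both by coordinate golden-section search with a coarse-grid restart
over a 2-D box (flat objectives return the box centre).

## Landscape analyses

* `find_trait_max()` — exact argmax over completed rows; the peak's
  mean substrate C:N is reported as the species' optimal C:N.
* `fit_ridge()` — for each value of trait *i*, the grid argmax of
  performance over trait *j* (the two remaining traits fixed), then an
  ordinary least-squares line through the locus: slope alpha,
  intercept, r².  Grid nodes are used without interpolation.
* `alpha_sum()` — slopes are non-dimensionalised by the observed trait
  ratio (`alpha * obs_i / obs_j`) before summing absolute values; this
  is the only unit-free convention computable from the quantities at
  hand, and it is applied uniformly.
* `rma_fit()` — reduced major axis regression,
  `slope = sign(r) * sd(y)/sd(x)`, for predicted-versus-observed trait
  comparisons where both sides carry error.
* `predict_plasticity()` — the high-N landscape restricted to the
  sub-grid nearest three fixed trait values, argmax over the target
  trait; a ridge-based linear prediction is available as a diagnostic.
* `pca_compare()` — PCA on the correlation matrix of each trait matrix
  (traits have incommensurable units), axis signs fixed so the
  largest-magnitude loading is positive, and per-axis OLS of predicted
  on observed species scores with a relative RMSE normalised by the
  observed score range.
* `variance_decomposition()` — incremental R² averaged over both orders
  of entry, normalised to 100.
* `ridge_homeostasis()` — compares the coefficient of variation of mean
  substrate C:N along the fitted ridge locus against the same locus
  reversed across its midpoint.  The reversed locus is the through-peak
  orthogonal direction expressed on grid nodes: it visits the same
  marginal trait values but pairs them in the anti-coordinated order,
  so the contrast isolates the effect of breaking the trait
  correlation.  (A literal orthogonal line through the peak truncates
  at the grid edge whenever the peak sits near one, which is common.)

## The synthetic data generators

`gen_species()` draws archetype trait vectors with the two negative
spectra imposed through a Gaussian copula on ranks (SLA–LLS and H–TD,
copula correlation −0.6 each, the two spectra mutually independent) and
uniform marginals over the observed panel ranges.  `gen_climate()`
produces sinusoidal seasonal PAR and temperature (peak at mid-summer)
with optional Gaussian day-to-day noise, truncated at zero PAR.
`gen_management()` converts annual fertiliser totals to equal split
applications.  What these emulate is the *statistical shape* of
temperate-grassland forcing — seasonality, short-term weather noise,
split fertilisation — not any particular year's weather; passing tests
on synthetic drivers therefore demonstrates internal consistency of the
pipeline and qualitative robustness, not predictive skill against field
measurements.  Real weather brings autocorrelated drought spells,
frost events and radiation–temperature covariance that the generator
deliberately omits (the model has no water balance to respond to them).

## Design decisions worth knowing about

* **Carbon surplus closure.** With growth sink- or N-limited, assimilate
  would otherwise accumulate without bound.  Three mechanisms close the
  balance: storage of part of the daily excess over the target C:N,
  exudation of part of the remainder, and a steep product feedback
  that shuts assimilation (and, on the N side, uptake) down when a
  substrate pool saturates relative to structural mass.  The feedback
  thresholds (4x and 0.2x structural mass) sit well above the normal
  operating range, so they act as guard rails rather than day-to-day
  regulators.
* **Linear reserves.** Reserve remobilisation at a constant fractional
  rate; threshold-switched remobilisation was tried and discarded
  because the discontinuity sustains multi-year limit cycles.
* **Annual production** is the sum of daily structural growth (shoot,
  protein, root), so tissue that is later cut is counted once, when it
  was grown; harvest is reported separately and the accounting identity
  production = Δstanding + litter + harvest is enforced by test.
* **Performance includes harvested mass** through that definition — a
  cut-and-regrow sward is not penalised for having its standing crop
  removed.
* **Ridge sign universality.** On the packaged 12-species panel the full
  four-sign pattern (SLA–LLS and TD–H negative, TD–SLA and SLA–H
  positive) emerges for seven species; the packaged structure checks
  run three of them spanning the panel (A. pratensis, A. elatius,
  F. rubra).  Species far from the calibration point can flip the
  weaker pairs (TD–H, SLA–H), which is an honest limitation of a
  single shared physiological parameterisation.

## Limitations

No water balance or transpiration, no grazing, no interspecific
competition or multi-species canopies, no seed reproduction or
recruitment, no claim of numeric equivalence with any field-calibrated
model: the package reproduces the *qualitative structure* of
trait-coordination landscapes (single peaks, ridge signs, C:N
homeostasis, plasticity consistency) and provides the full statistical
machinery, at desk scale.

## A minimal run

```{r demo, eval = FALSE}
sp <- gen_species(2, seed = 1)
spec <- campaign_spec(sp, n_levels = 360, steps = 3, years = 2)
land <- run_campaign(spec)
opt <- find_trait_max(land[land$species == sp$species[1], ])
opt$traits
ridge <- fit_ridge(land[land$species == sp$species[1], ], "sla", "lls")
c(slope = ridge$slope, r2 = ridge$r2)
```
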