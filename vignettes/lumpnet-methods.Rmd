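---
title: "Deriving balanced lumped reactions from genome-scale models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving balanced lumped reactions from genome-scale models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumpnet)
```

## The model

A constraint-based metabolic model is a stoichiometric matrix $S$ over
metabolites (rows) and reactions (columns) with flux bounds
$lb_i \le v_i \le ub_i$ and the quasi-steady-state assumption $S v = 0$.
`lumpnet` partitions the reactions into a user-chosen **core** $R^{core}$
(classically: glycolysis, pentose phosphate pathway, TCA cycle, by-product
formation, part of the electron transport chain), a set of **always-on**
reactions exempt from gating (boundary exchanges when so configured, target
drains, the biomass reaction), and the remaining **non-core** set
$R^{nc}$.  The metabolites touched by core reactions, plus explicitly
listed cofactor pairs and inorganics, form $M^{core}$ — the allowed
precursor pool.

### Biomass decomposition

The biomass reaction is decomposed exhaustively into (i) individual
building-block demands $n_j$ (mmol/gDW, substrates; products such as
diphosphate are kept with a `produced` role), (ii) growth-associated
maintenance (GAM), extracted as the largest $\alpha$ such that
$\alpha\,(\mathrm{ATP} + \mathrm{H_2O} \to \mathrm{ADP} + \mathrm{P_i} +
\mathrm{H})$ fits inside the biomass stoichiometry, and (iii) the
adenylate imbalance — the ATP/ADP remainder after removing GAM, which is a
net demand for de-novo adenylate synthesis.  The decomposition is lossless
(`biomass_stoich()` reconstructs the original column exactly), and GAM,
the adenylate imbalance and produced by-products can all be targeted like
ordinary building blocks (`gam_stoich()` + `add_demand_reaction()`,
`role = "produced"` drains).

### The minimal-subnetwork MILP

Every reaction is split as $v_i = F_i - B_i$ with $F_i, B_i \ge 0$
(irreversible reactions get $B_i = 0$ fixed), and every non-core reaction
receives a binary $z_i$ with the gating constraint

$$F_i + B_i + C\,z_i \le C ,$$

which closes the reaction in *both* directions when $z_i = 1$ and relaxes
to the flux cap $C$ when $z_i = 0$ — gating is direction-unbiased.  For
target $j$, a drain reaction is forced to carry $v_{sink,j} \ge n_j
\mu_{max}$ (with $\mu_{max}$ from FBA of the parent model at the configured
medium; non-biomass targets fall back to an absolute $10^{-3}$ flux
demand), and the objective maximizes $\sum_i z_i$.  The reactions left open
at the optimum are the smallest subnetwork able to synthesize the target
from $M^{core}$ — at a maximum of $\sum z_i$ no unnecessary gate stays
open, so no flux-based pruning is applied.  Alternatives are enumerated by
appending the integer cut $\sum_{k \in R^{sub}} z_k \ge 1$ after each
solution (the strict "greater than zero" form is meaningless over binaries
and is implemented as $\ge 1$).  In minimal-only mode enumeration stops
when the optimum's size first exceeds the minimum; since all minimal
subnetworks share one cardinality and none contains another, the collected
sets are exactly the minimal collection, independent of solver tie-breaks.
Discovery *order* among equally small subnetworks is solver-dependent and
deliberately not part of the tested contract; the *set* is.

### Lumping

On the core + subnetwork + drain model, the flux distribution is fixed by
minimizing $\sum_{i \in R^{sub}} (F_i + B_i)$ at $v_{sink} = d$ — the L1
minimum makes the subnetwork's fluxes stoichiometrically proportional, so
the lump

$$\mathrm{coeff}(m) = \frac{1}{v_{sink}} \sum_{i \in R^{sub}} S_{mi} v_i$$

is the exact per-mmol cost of the target.  Only core metabolites, the
target and drained by-products may survive; any non-core intermediate above
$10^{-6}$ aborts with a dedicated condition, since it signals a flux
distribution that is not steady for the subnetwork alone.  Coefficients are
normalized to target $+1$ and snapped to rationals with denominator at most
48 (continued fractions; values with no such rational within $10^{-6}$ pass
through as floats), which recovers the small-integer stoichiometries these
lumps have in practice and makes the elemental audit exact.  Because every
member reaction balances, the lump's element and charge residuals are zero;
`audit_elemental_balance()` verifies rather than assumes this.

The L1 problem can have alternative optima that yield different lumps for
one subnetwork.  A second solve with a deterministically jittered objective
(relative $10^{-7}$, seeded from the subnetwork's reaction ids) detects
this; a differing lump sets `attr(lump, "degenerate")` and the solver's
optimum is reported.

## Parameters that matter

* **Flux cap `C`** (flux units, default `default_carbon_cap()`): with a
  single bounded carbon source, $C$ = (carbon atoms) × (uptake bound),
  e.g. $6 \times 10 = 60$ for glucose at 10 mmol/gDW/h — the total
  carbon-atom influx bounds every carbon-carrying flux, and the smallest
  valid big-M gives the tightest MILP relaxation.  With several or
  unbounded carbon sources a configured big-M (1000) stands in.
* **Demand** (mmol/gDW/h): $n_j \mu_{max}$ per target.  Scaling the demand
  does not change the lump (tested property), only feasibility margins.
* **Gating scope**: transports are gated like enzymatic reactions —
  compartmentalized models need no special treatment, transports simply
  become subnetwork members; `gate_transports = FALSE` exempts boundary
  exchanges.  Drains of *other* targets are closed (not gated) during each
  target's solve, so subnetworks cannot discard by-products through them
  for free.
* **Tolerances**: MILP integrality $10^{-6}$ and feasibility $10^{-8}$
  (HiGHS defaults; binaries are rounded at 0.5 before set extraction),
  lump cleanup $10^{-6}$, verification slack $10^{-9}$.

## Thermodynamic directionality

Full thermodynamics-based flux analysis couples Gibbs-energy variables and
direction binaries inside the MILP.  This package instead treats
thermodynamics as a pluggable pre-pass, which is the natural fit for a
mass-balance-first tool: user-supplied standard transformed Gibbs energies
$\Delta G'^\circ$, uncertainties and metabolite concentration ranges give
the closed-form range of $\Delta G' = \Delta G'^\circ + RT \sum_m n_m \ln
c_m$ over the concentration boxes; a direction is admitted only if its
$\Delta G'$ can be negative.  The resulting bounds are never wider than the
model's own, can be scoped to core reactions only, and with empty data the
pipeline output is identical to mass-balance-only mode (tested).  In-MILP
thermodynamic variables are out of scope.

## Yield ranking and model reduction

Each lump is evaluated on its own "mini" model — core reactions, boundary
exchanges over the retained species, the lump, the target drain, nothing
else — by maximizing the drain and reporting C-mol yield
$(\mathrm{C}_{target}\, v_{sink}) / (\mathrm{C}_{source}\, v_{uptake})$ at
the medium's uptake bound.  Yields are per-lump even when several lumps
coexist in a reduced model, and carbon conservation bounds them by 1 on
single-source media (asserted on every audited run).  Ranking is descending
by yield with deterministic ties (lump size, then equation string).

For reduction, all deduplicated lumps enter one candidate model (core +
lumps + parent boundary/transport reactions over retained species +
biomass).  FBA gives $\mu^\*$; the selection MILP fixes $v_{biomass} \ge
\mu^\*(1 - 10^{-6})$ (inequality, not equality — MILP numerics), gates each
lump with a binary, and minimizes the number of active lumps.  The reduced
model must re-attain $\mu \ge \mu^\*(1-10^{-4})$; every selected lump is
load-bearing (removing one drops growth below the fixed yield, tested), and
$\mu_{reduced} \le \mu_{parent}$ always, because the reduced feasible set
is a restriction.

## What the synthetic fixtures emulate — and what they do not

`make_toy_gem()` builds models with a glucose-like C6 source, a linear core
chain to a precursor, NAD(P)-style cofactor pairs with core regeneration,
and per target several disjoint synthesis routes.  Routes shed side
metabolites that only a dedicated balancer reaction can convert to a
secretable species — the toy analogue of the branched subnetworks that mass
balance forces onto linear textbook pathways — plus dead-end decoys and
optionally a longer redundant route.  Formulas are assigned by integer atom
bookkeeping so every reaction balances exactly, making end-to-end elemental
audits meaningful without real chemistry.  The generator is fully
seed-deterministic, and each emitted fixture's ground truth is re-certified
against the exhaustive oracle by default.

These fixtures exercise the full algorithmic surface (branching, gating,
integer cuts, cofactor-variant lumps, redundant-lump selection) at sizes —
up to ~14 non-core reactions, 2 targets — where exhaustive enumeration is
possible: `brute_force_min_subnetworks()` tests subsets by increasing
cardinality with an LP per subset, and at the first feasible cardinality
every feasible subset is provably inclusion-minimal.  What the toys do
*not* emulate: genome-scale combinatorics (hundreds of alternative routes
for lipids), compartmentalized transport costs, thermodynamically infeasible
cycles, missing formulas, and the degenerate cofactor swaps of real GEMs.
Passing the desk-scale suite therefore certifies algorithmic correctness,
not genome-scale performance; the genome-scale workflow is exercised via
`scripts/gem_benchmarks.R` on user-supplied models.  Problem sizes in the
test suite (50 certified fixtures for oracle equivalence, 8–12 for lumping
and recovery, 3–4 reduction toys) were chosen as the smallest battery that
covers every layout class the generator can produce.

## Numerical and design choices

* Stoichiometric coefficients are snapped at load time to rationals with
  denominator $\le 10^6$; the lumping step's exact cancellations then
  survive double arithmetic comfortably within the $10^{-6}$ tolerances.
* Reversibility is encoded purely via bounds; splitting applies to *all*
  reactions for uniform L1 handling, with backward parts of irreversible
  reactions fixed at zero.  Splitting preserves the FBA optimum to
  $10^{-9}$ (tested).
* The biomass cofactor question — whether paired species (NAD/NADH, CoA)
  are targeted in oxidized, reduced or both forms — is left per-target:
  targets are plain metabolite ids, so callers choose either or both.
* Periplasmic/extracellular species of core reactions count as core
  metabolites (they are metabolites *of* core reactions); the partition
  accepts extra core metabolites for anything else.
* Whether published genome-scale alternative counts were produced with or
  without active thermodynamic cuts is not decidable from the available
  material; this package's default is mass-balance-only, with
  `directionality_bounds()` as the opt-in tightening pass.
* Solver determinism: HiGHS runs single-threaded with a zero MIP gap; the
  enumeration loop lives in the solver worker to amortize interpreter
  start-up, but R re-verifies every returned subnetwork (feasibility and
  single-deletion minimality) independently.

## Known limitations

Gene–protein–reaction logic, automated core selection, elementary-flux-mode
computation, ΔG estimation for lumps, and kinetic parameterization of
reduced models are out of scope.  Very large `up-to-size` enumerations can
hit `max_count`; truncation is flagged on the result, never silent.
Metabolites without chemical formulas are tolerated throughout but excluded
from elemental audits and carbon-yield computation, and are reported as
unaudited.
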