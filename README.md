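# lumpnet

Minimal biosynthetic subnetworks and elementally balanced lumped reactions
for constraint-based metabolic models.

## The problem

Genome-scale metabolic models (GEMs) contain every known reaction of an
organism, but many analyses — metabolic flux analysis, kinetic modelling,
classroom-sized core models — want a *small* network whose biomass
requirements are still consistent with the full model.  Classical core
models (glycolysis, pentose phosphate pathway, TCA cycle, part of the
electron transport chain) handle this with one hand-curated "lumped"
reaction per biomass building block (amino acid, nucleotide, lipid, …),
stating how much precursor, ATP, NAD(P)H and nitrogen its synthesis costs.
Those hand-made lumps are rarely elementally balanced, and they ignore that
real networks hold many alternative routes.

`lumpnet` derives such lumped reactions systematically from a GEM.  For each
target metabolite *j* with biomass demand *n<sub>j</sub>* it solves the
mixed-integer linear program

```
maximize   sum_i z_i                    (i over non-core reactions)
subject to S v = 0                      (steady state)
           F_i + B_i + C z_i <= C      (binary gating, v_i = F_i - B_i)
           v_sink,j >= n_j * mu_max    (forced synthesis flux)
```

so the reactions with `z_i = 0` form the **smallest balanced subnetwork**
able to synthesize the target from the core metabolites.  Because mass
balance is enforced for every species, these subnetworks are generally *not*
the linear textbook routes: they contain branches that consume or regenerate
whatever the linear route leaves unbalanced.  Appending the integer cut
`sum_{k in subnetwork} z_k >= 1` and re-solving enumerates all alternative
minimal subnetworks.  Each subnetwork is collapsed into one overall reaction
by minimizing the L1 norm of its net fluxes at fixed target demand and
summing its stoichiometric columns weighted by flux — a lump that contains
only core metabolites, the target, and secreted by-products, and whose
elemental/charge balance the package audits to zero.  Alternative lumps are
ranked by carbon-mole yield (C-atoms in target flux per C-atom of substrate
uptake) on per-lump "mini" models, and a second MILP assembles a reduced
model: core + lumps + boundary reactions + biomass, with the number of
active lumps minimized at the fixed maximal growth rate.

LP/MILP instances are solved with HiGHS through a bundled SciPy worker
script (`inst/python/milp_worker.py`); Python ≥ 3.9 with `numpy` and `scipy`
must be on the `PATH`.

## Worked example

The package ships a seeded toy-model generator whose ground truth (minimal
subnetworks *and* their lumps) is known by construction and certified by an
exhaustive oracle.  The default layout plants two disjoint 3-step routes
from the core precursor to one target, plus a side metabolite that only a
dedicated "balancer" reaction can dispose of:

```r
library(lumpnet)

toy <- make_toy_gem(toy_spec(planted_paths = list(list(c(3, 2))),
                             branch_balancers = 1, seed = 7))
gt  <- toy$ground_truth[["bbb1_c"]]

sg      <- split_and_gate(toy$model, toy$partition)
problem <- subnetwork_problem(sg, "sink_bbb1_c", gt$demand)
alts    <- enumerate_alternatives(problem)
alts[[1]]
#> <subnetwork for 'bbb1_c': 4 reaction(s): BAL1, PATH_t1_p1_s1,
#>   PATH_t1_p1_s2, PATH_t1_p1_s3>
```

Both alternatives have size 4 — each 3-step route *plus* the balancer, which
mass balance makes mandatory.  Collapsing and deduplicating:

```r
lumps <- lapply(alts, function(sn) {
  flux <- minimize_net_flux(toy$model, toy$partition, sn)
  build_lump(sn, flux, toy$model, toy$partition)
})
unique_lumps <- dedupe_lumps(lumps)
unique_lumps[[1]]
#> <lumped_reaction 'bbb1_c'>
#>   nad_c + pre_c -> bbb1_c + nadh_c + w1sec_c
unique_lumps[[1]]$balance_report
#>      C      H      N      O charge
#>      0      0      0      0      0
```

The two routes collapse to the *same* overall reaction (one lump from two
subnetworks): one precursor and one NAD are spent per target, one reduced
cofactor and one secreted by-product come back, and every element balances
exactly.  Its carbon-mole yield on the glucose-like source:

```r
rec <- cmol_yield(build_mini_model(toy$model, toy$partition, unique_lumps[[1]]),
                  "bbb1_c", "src_c", lump = unique_lumps[[1]])
rec
#> <yield_record: bbb1_c from src_c, C-mol yield 0.8333>
```

For genome-scale work the same functions apply to a loaded model
(`load_model("iJO1366.json")`, `parse_biomass()`, `add_target_sinks()`,
`define_core()` with a core reaction list, then `generate_lumps()`);
`scripts/gem_benchmarks.R` wraps that workflow for user-downloaded GEMs,
and `inst/exec/lumpnet` is a shell entry point over the same pipeline.

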