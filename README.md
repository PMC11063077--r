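# crnsteer

Operator-steered, reproducible exploration of chemical reaction
networks (CRNs), at desk scale.

Automated mechanism exploration discovers elementary reaction steps by
*single-ended* trials: reactive atom pairs are forced together or
apart, a transition-state (TS) guess is harvested from the forced
trajectory, and validated steps are aggregated into a network of
compounds, flasks and reactions.  Unguided, the number of candidate
trials explodes combinatorially.  `crnsteer` implements a steering
layer for such explorations — for computational chemists who want to
drive an exploration toward a mechanistic question without
pre-defining its intermediates, and to publish a protocol that
reproduces the run exactly.

An exploration is an ordered protocol alternating two step kinds:

* **Selection Steps** restrict the network to a subset of aggregates,
  structures and reactive sites (all compounds, products of the last
  expansion, a central metal and its coordination sphere, energy
  criteria such as the *n* lowest conformers, structural motifs);
* **Network Expansion Steps** set up calculations (association,
  dissociation, rearrangement, conformer generation, optimization),
  wait for *all* of them to finish, and classify the results into the
  store.

Completion gating plus per-step seeding makes runs byte-reproducible:
two runs of one protocol export identical stores, and an interrupted
run resumed from its checkpoint equals an uninterrupted one.

The scientific core follows the single-ended trial methodology:

* TS-guess selection from a scan profile by rule cascade — last local
  energy maximum before the bond-order change event (a Savitzky–Golay
  smoothed screen decides whether one was observed), else first
  maximum after the event, else the highest maximum when no event
  occurred;
* force scaling for haptic (η<sup>n</sup>) coordinates, detected from
  bond orders, so a k-pair group applies one pair's worth of force;
* a fast dissociation screen enumerating homo-/heterolytic charge
  splits and parity-consistent spin multiplicities, with a barrierless
  probe (fragments re-placed at van-der-Waals contact; recovery of the
  parent aggregate adds a TS-free step) and a 200 kJ/mol follow-up
  rule for scan-based verification;
* de-duplication by aggregate identity: equal charge, spin
  multiplicity, and element-labelled molecular-graph isomorphism;
* k-lowest-energy path search on the bipartite compound/reaction
  graph, with co-reactant acquisition costs and level-diagram export.

Electronic structure is abstracted behind a calculator contract; the
shipped engine is a deterministic pairwise-Morse surrogate
(`toy_calculator()`) so that every component runs in seconds and every
expected value is independently checkable.  Real engines can be
slotted in behind the same contract.

## Worked example: a ligand exchange in six steps

The `ligand-exchange` fixture is a metal hydride M–H plus a free
oxygen ligand.  Its protocol optimizes the inputs, associates O at the
metal, then screens the M–H bond for dissociation:

```r
library(crnsteer)

fx   <- make_fixture("ligand-exchange", seed = 1)
calc <- toy_calculator(fx$potential)
res  <- run_protocol(fx$protocol, calculator = calc,
                     input_structures = fx$structures)
res$store
#> <crn_store> structures=9 compounds=5 flasks=2 elementary_steps=2 reactions=2 calculations=4
```

Nine structures were sorted into five compounds and two flasks, and
two reactions were recorded.  Both are barrierless on this surface —
the association of O onto M and the screened loss of the hydride:

```r
#> r000001: c000003 -> f000001  Ea(fwd) 0.0 kJ/mol  dE 266.4 kJ/mol  barrierless
#> r000002: c000003 -> f000002  Ea(fwd) 0.0 kJ/mol  dE 253.5 kJ/mol  barrierless
```

`c000003` is the three-atom H–M–O complex (empirical formula `HMO`,
electronic energy −473.5 kJ/mol on the surrogate surface); `f000001`
and `f000002` are the flasks holding its separated fragments, 266.4
and 253.5 kJ/mol uphill.  Since 253.5 > 200 kJ/mol, the hydride loss
is recorded through the barrierless probe rather than queued for a
follow-up scan.

Path analysis works on any store with energies.  The
`toy-monsanto-shape` fixture embeds two routes to one product
diverging at one intermediate:

```r
net   <- make_fixture("toy-monsanto-shape", seed = 1)
bs    <- build_fixture_store(net)
pg    <- build_graph(bs$store, start = bs$ids[["A"]])
paths <- find_lowest_paths(pg, bs$ids[["A"]], bs$ids[["P"]], k = 5)
vapply(paths, `[[`, 0, "cost")
#> [1] 100 120
export_level_diagram(paths[[1]])
#>      species energy             kind
#> 1    c000001      0          minimum
#> 2 r000001:TS     50 transition-state
#> 3    c000002    -10          minimum
#> 4 r000002:TS     20 transition-state
#> 5    c000003    -15          minimum
#> 6 r000004:TS      5 transition-state
#> 7    c000005    -40          minimum
```

The returned routes are cost-ordered (100 before 120 kJ/mol) and the
diagram lists relative energies referenced to the first species, with
TS records where a saddle was validated.

A thin command-line front end ships at `inst/scripts/explore`
(`run`, `preview`, `report`, `paths`, `import-deposit`,
`gen-fixtures`), e.g.:

```sh
Rscript inst/scripts/explore gen-fixtures ligand-exchange --seed 2 --out fxdir
Rscript inst/scripts/explore run fxdir/protocol.yaml storedir \
        --potential fxdir/potential.yaml --inputs fxdir
```

## Scope

The package validates exploration *machinery*, not chemistry: the
surrogate potential has no valence saturation, no solvation and no
real thermochemistry.  See the methods vignette
(`vignettes/steering-crn-exploration.Rmd`) for the models, parameter
defaults, design decisions and known limitations.
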