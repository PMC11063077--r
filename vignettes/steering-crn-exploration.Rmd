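---
title: "Steered exploration of chemical reaction networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steered exploration of chemical reaction networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnsteer)
```

# The problem

Automated mechanism exploration grows a chemical reaction network (CRN)
by running many single-ended reaction trials: pairs of reactive sites
are pushed together or pulled apart, a transition-state (TS) guess is
harvested from the forced trajectory, and validated elementary steps
are sorted into a growing graph of compounds, flasks and reactions.
Left unguided, the number of candidate site pairings explodes
combinatorially.  `crnsteer` implements an operator-steering layer over
such an exploration: the run is split into an ordered, serializable
protocol of alternating *Selection Steps* (which restrict the
aggregates, structures and reactive sites considered next) and *Network
Expansion Steps* (which set up calculations, wait for all of them to
finish, and classify the results into the store).  Because a step may
start only when the previous one is complete, a published protocol plus
the inputs and the engine reproduce the exploration exactly.

This package is desk-scale by design: the electronic-structure engine
is abstracted behind a calculator contract, and the shipped engine is a
deterministic surrogate (below).  Every algorithmic component —
aggregation by graph isomorphism, scan driving, TS-guess selection,
haptic force scaling, dissociation screening, path search — runs in
seconds on toy systems, which is what makes the property-based test
suite and the reproducibility guarantees checkable at all.

# The data model

A **structure** is one 3-D geometry with total charge $q$ and spin
multiplicity $M_s$; electron-count parity must match multiplicity
parity, which `structure_new()` enforces.  Structures that share $q$,
$M_s$ and an element-labelled molecular graph belong to one aggregate:
a **compound** when the graph is connected, a **flask** when it is a
non-covalent complex of two or more molecules (a flask also references
the compounds of its constituents).  An **elementary step** connects
stored structures either through one TS or barrierlessly; steps whose
endpoint aggregate sets coincide (direction-normalized) aggregate into
one **reaction**, which carries the minimal forward/backward activation
energies over its members.  **Calculation** records follow a monotone
pending → running → done/failed lifecycle, so "every calculation
finished" is a checkable gate.

Graph identity uses element labels only; stereoisomers are distinct
structures within one compound.  Identity testing runs an iterative
colour-refinement certificate as a cheap pre-filter and confirms with
exact VF2 isomorphism (vertex-coloured) on certificate agreement; the
test suite pins this against brute-force permutation search for graphs
up to eight atoms.

Bond perception takes calculator (Mayer-style) bond orders when the
engine provides them and otherwise falls back to a covalent-radius
rule: a bond when $d \le 1.25\,(r_A + r_B)$ with Pyykkö single-bond
radii.  The bond-order detection threshold defaults to 0.30, so a weak
contact of order 0.22 at 2.6 Å is classified non-bonded by both
criteria.  Both knobs are arguments, not constants.

# The surrogate calculator

The shipped engine evaluates

$$E = \sum_{i<j} D_{ij}\left[(1 - e^{-\beta_{ij}(d_{ij} -
r^0_{ij})})^2 - 1\right] \;+\; A\,e^{-b\,d_{ij}}\;[\,D_{ij}=0\,]
\;+\; E_\mathrm{off}(\mathrm{formula}, q, M_s),$$

a sum of pairwise Morse wells over tabulated element pairs (kJ/mol,
Å), a pure exponential core repulsion for pairs tabled with zero well
depth, and an additive whole-structure offset.  The offset falls back
to $k_q q^2 + k_m (M_s - 1)$ (defaults 150 and 80 kJ/mol) and can be
overridden per (formula, charge, multiplicity) — this is what makes
the dissociation screen's charge/multiplicity enumeration produce
distinguishable energies without any quantum mechanics.  Gradients are
analytic; bond orders follow a Pauling relation
$n(d) = e^{(r_0 - d)/b}$ with width 0.35 Å.

The form is smooth, deterministic, translationally and rotationally
invariant, and size-consistent for offset-free (neutral singlet)
fragments; these are asserted as properties in the tests.  Because the
offsets attach to whole structures rather than to fragments, strict
size-consistency across charged or spin-excited fragment partitions is
not claimed.

Two deliberate limitations matter for interpreting results.  First,
pairwise Morse attraction has no valence saturation: any two atoms with
a tabled well attract, so plain associations are barrier-free and an
unconstrained cluster of mutually attractive atoms collapses to a
fully bonded minimum.  Activation barriers therefore arise only from
steric core repulsion or from concerted forming/breaking coordinates.
Second, fragments placed at van-der-Waals contact always re-associate
on this surface, so the barrierless probe's negative outcome (the
supersystem *not* recovering the parent) occurs only through engine
failure, not through a genuinely repulsive approach.  Passing tests
therefore validate the machinery — classification logic, bookkeeping,
determinism — not chemistry.

Minimization is quasi-Newton (L-BFGS-B) with analytic gradients,
gradient-infinity-norm tolerance $10^{-6}$ kJ/mol/Å and at most 500
iterations; non-convergence is flagged, never silently accepted.
Constrained relaxation (the scan workhorse) runs an escalating
quadratic-penalty minimization ($k = 10^4$, then $10^6$), projects the
constrained pair distances exactly onto their targets, and finally
relaxes the unconstrained atoms; constrained distances end within
$10^{-3}$ Å of target and reported energies are penalty-free.  For a
diatomic this makes scan profiles agree with the Morse closed form to
machine precision, which the tests exploit.

# Reaction trials

A **reaction coordinate** is a list of atom pairs tagged associative or
dissociative with per-pair force scales.  Bimolecular complexes place
the second fragment so the primary site pair faces at the start
separation (default: the sites' van-der-Waals radii sum), sampling
rigid orientations deterministically from a seed until no clash
remains.  A scan moves each pair's distance by
$\mathrm{scale} \times \mathrm{step}$ per macro-iteration (default 0.1
Å, at most 200 steps), relaxes everything else under the constraints,
and records geometry, penalty-free energy and bond orders per frame.
It stops when the requested bond-order change is reached (formation
rising above, cleavage falling below, threshold 0.5), at the step
limit, or on a calculator failure — the truncated trajectory stays
analyzable, with the reason recorded.

**TS-guess selection** implements a three-rule cascade on the energy
profile.  If the bond-order change occurred: take the last local
maximum before the event; whether any maximum was observed before the
event is decided on the profile smoothed with a Savitzky–Golay filter
(window 5 frames, polynomial order 2 — the smallest symmetric quadratic
smoother), so single-frame noise cannot satisfy the screen.  If the
smoothed screen finds nothing before the event, take the first local
maximum after it.  Without an event, take the highest local maximum.
Frame selection itself uses the raw profile: the smoothing decides
*whether*, the raw maxima decide *which* — the combination is the only
reading under which small integer profiles behave sensibly (e.g.
profile $(0,5,2,8,1)$ with the event at the fourth frame selects the
second).  Maxima are strict against both neighbours; plateaus resolve
to their first frame; endpoints never qualify; a profile with no
interior maximum yields an explicit no-guess result.  An independent
brute-force oracle (`ts_guess_oracle()`, exhaustive enumeration plus a
per-window polynomial least-squares smoother) is exercised against the
implementation on a thousand random profiles.

**Haptic force scaling** detects, from current bond orders, groups of
same-kind coordinate pairs that target one chemical bond — pairs
sharing a nucleus, or whose endpoints sit adjacent on one contiguous
bonded fragment (an $\eta^n$ coordination) — and scales each pair in a
$k$-pair group by $1/k$, so the group applies a single pair's worth of
force and concerted coordinates elsewhere keep their full force.

**Validation** refines the guess by 1-D maximization along the local
trajectory direction, relaxes downhill from both displaced sides, and
accepts only when the two sides reach *different* molecular graphs
with the refined TS at least as high as both endpoints; everything
else is a rejection with a reason.  When a scan reaches its bond-order
target with no interior maximum at all — the signature of a downhill,
barrier-free event on this surface — the expansion machinery instead
compares the optimized final frame against the starting arrangement
and records a barrierless step when the graphs differ.

**Dissociation screening** deletes the chosen bonds, splits the parent
into fragments, and optimizes every fragment separately for all
enumerated charge splits (each fragment within ±1 of zero, shifted
toward the parent charge, summing to it — homo- and heterolytic) and
all spin multiplicities up to the parent's plus one whose parity
matches the fragment electron count.  The per-fragment parity rule
replaces a naive parent-centred multiplicity window because a
closed-shell parent must be allowed closed-shell heterolytic fragments
(singlet anion plus singlet cation), which a $\{M_s\pm1\}$ window
forbids.  The lowest-energy combination defines the dissociation
energy.  The **barrierless probe** then aligns the optimized fragments
back onto their parent positions (Kabsch), elongates the cut bond to
the sum of the reactive sites' van-der-Waals radii, and optimizes the
supersystem: recovery of the parent's aggregate key adds a TS-free
elementary step.  After a screening pass, exactly the dissociations
with reaction energy below 200 kJ/mol are queued for conventional
scan-based follow-up; the threshold applies to electronic energies.

# Steering

Protocols parse from the compact bracketed keyword list used in
publications (`[File_Input_Selection, Dissociation, ...]`) or from a
structured YAML form carrying per-step settings, the model tag and the
seed; serialization round-trips losslessly and version mismatches are
flagged.  Expansion-only listings (consecutive expansions, as published
protocols often are) are accepted by default, reusing the prior
selection implicitly; `strict = TRUE` enforces alternation.  The
expansion sub-list helper omits Selection steps and, by default,
leading preparation optimizations — the convention used when a
protocol's expansion list is quoted.

Selection kinds: explicit file input; all current aggregates; the
aggregates first created by the immediately preceding expansion
(products); aggregates containing a configured central metal with
sites restricted to its graph vicinity (default: two bonds — the
coordination sphere); energy criteria ($n$ lowest conformers,
maximum-diversity conformer subsets by farthest-point clustering on
best-fit RMSD, or aggregates reachable within an activation-energy
cutoff); and structural-motif containment (subgraph isomorphism).
Combining several selections conjoins them — aggregate sets intersect
and both site filters must accept — which never enlarges the search
space, an invariant the tests assert.

Expansions enumerate their trials deterministically from the selection
(`preview_expansion()` returns exactly the multiset `run_expansion()`
executes, without writing calculations): associations between
aggregate pairs passing element-composition filters, dissociations of
graph-disconnecting bonds, unimolecular rearrangements combining a
forming pair with an adjacent breaking bond, rotamer generation on a
torsion grid with RMSD-gated (0.1 Å) de-duplication, and plain
optimizations.  The number of sampled coordinates per trial pair
defaults to 1 and is a per-step setting.  Every trial gets a
calculation record; failures are recorded and do not abort the step.

`run_protocol()` executes steps strictly in order, derives a per-step
RNG seed from the protocol seed, records a hash of every completed
step in the store, and refuses to resume a store whose completed
prefix does not hash-match the supplied protocol — extending a
finished protocol with further steps is allowed, silently mutating
history is not.  Store exports are byte-deterministic: records are
written in sorted-id order with fixed field order, and all persisted
numerics are quantized at the store boundary (coordinates to $10^{-10}$
Å, energies to $10^{-8}$ kJ/mol) so that values survive the JSON text
round-trip exactly.  Two runs with one seed export byte-identical
stores, and interrupt-plus-resume equals an uninterrupted run — both
are acceptance-tested on the polymerization fixture.

# Pathfinding

The store maps onto a bipartite directed graph: aggregate nodes and
one node per reaction direction, with edge cost equal to that
direction's activation energy (zero for barrierless reactions,
following the convention of labelling such reactions 0.0 regardless of
endo-/exothermicity).  A reaction requiring aggregates beyond the one
the path enters through charges their *acquisition cost*: the cheapest
cost of making each co-reactant from the start set, computed as a
memoized Bellman–Ford fixpoint.  This is a deliberately simplified
compound-cost scheme — it prices each co-reactant independently and
ignores stoichiometric coupling between branches — and it is pinned by
a dedicated test rather than hidden.  Costs are raw activation
energies, matching the "energetically lowest path" reading; other
weightings can be layered on the same graph.

k-lowest loopless paths come from Yen-style deviation search
(`igraph::k_shortest_paths`) with deterministic tie-breaking by node-id
sequence; an exhaustive simple-path enumerator serves as the oracle on
networks of up to a dozen aggregates.  `export_level_diagram()` turns a
path into the ordered record table behind an energy level diagram
(minima, TS levels at cumulative energy plus activation, barrierless
links), referenced to the path's first aggregate and therefore
invariant under global energy shifts.

# The fixture generator

`make_fixture(name, seed)` is a pure function of its arguments (the
caller's RNG stream is saved and restored).  The registered systems
emulate, at toy scale, the *shapes* of steered-exploration campaigns:

* `diatomics` — input handling and optimization-only protocols;
* `ligand-exchange` — a metal hydride gaining an oxygen ligand
  (association) and screening off the hydride (dissociation with a
  barrierless step): the smallest end-to-end exercise of both trial
  machineries;
* `toy-polymerization` — an M–C "catalyst" and a one-carbon monomer
  under an Association/Rearrangement protocol; each pair inserts one
  monomer into the metal-bound chain, echoing chain-growth catalysis;
  the ten-step protocol at this size runs in a few seconds, which is
  the problem size used for the byte-reproducibility checks;
* `toy-monsanto-shape` — a hand-energied five-species network with two
  cost-distinct routes (100 vs 120 kJ/mol) to one product diverging at
  one intermediate, the minimal shape of competing catalytic paths;
* `profile-suite` — random scan profiles (6–40 frames, rounded to one
  decimal so plateaus occur, with and without injected bond-change
  events) labelled by the independent TS-guess oracle.

What the fixtures deliberately do not emulate: real thermochemistry,
conformational richness, solvation, charge transfer beyond table
offsets, or any quantitative property of a real catalyst.  A green
suite means the exploration machinery is correct and reproducible on a
surface where every answer is independently checkable; transferring to
a real system means swapping the calculator behind the same contract.

# Numerical choices and degenerate inputs

Atoms closer than 0.1 Å are a degenerate-geometry error.  Associative
scan targets are floored at 0.5 Å.  Zero allowed scan steps yield a
single-frame trajectory with reason `max-steps`.  Conflicting distance
targets on one pair are an error; duplicated consistent targets are
merged.  Empty protocols are valid and do nothing.  Aggregates with no
recorded energies fall back to their first member as the
representative.  Ties in maxima (plateaus) break toward the earlier
frame; ties in path cost break by node-id sequence; both choices are
arbitrary but fixed, which is what determinism requires.

# Known limitations

Charge and multiplicity assignment of flask constituents created as
cross-references uses the neutral, lowest-parity-consistent state
rather than a physical partition.  The deposit reader resolves the
native layout fully but maps foreign MongoDB-export collections only
structurally (ids and counts); field-level semantics of external
deposits must come from the deposit's own description.  The haptic
grouping rule is a graph heuristic; exotic multi-centre coordinations
sharing no nucleus and no adjacency escape it.  Single-process
execution stands in for distributed workers; the calculation-record
lifecycle is kept so a queue backend can be slotted in without
touching the steering logic.
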