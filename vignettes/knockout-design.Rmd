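---
title: "Growth-coupled knockout design with a Bees Algorithm over ROOM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-coupled knockout design with a Bees Algorithm over ROOM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeknock)
```

## The problem

Deleting the right handful of genes can force a microbe to excrete a
valuable metabolite whenever it grows: if every route that competes with
the product pathway for carbon, redox or energy is removed, stoichiometry
alone couples production to biomass formation. Searching for such
deletion sets in a genome-scale metabolic model is a combinatorial
problem — ${2382 \choose 5}$ candidate reaction sets in an *E. coli*
reconstruction — wrapped around a non-trivial phenotype prediction for
each candidate. `beeknock` implements one hybrid answer: a Bees
Algorithm explores the knockout space, and each candidate is evaluated
through regulatory on/off minimization (ROOM).

## Phenotype prediction

### Wild-type reference

ROOM measures a mutant against a wild-type flux vector $w$, but FBA
optima are degenerate: many flux vectors attain maximal growth, and the
choice among them changes every downstream ROOM score. We therefore pin
$w$ down with parsimonious FBA: maximize biomass, then fix biomass at
its optimum and minimize $\sum_i |v_i|$. The second LP removes futile
cycles and gratuitous flux, and makes `wild_type_reference()` return the
same vector on every call — a precondition for reproducible fitness
values and for the byte-identical reports the test suite asserts.

### ROOM

The mutant flux distribution minimizes the *number* of significant flux
changes from $w$ (see the README for the full MILP). Two parameters
shape "significant":

* `delta` (default 0.03, dimensionless) — relative half-width of the
  tolerance window around each $w_i$;
* `epsilon` (default 0.001 mmol gDW⁻¹ hr⁻¹) — absolute half-width,
  which keeps the window non-empty for zero fluxes.

These are the defaults of the original ROOM formulation; the window is
$[\,w_i - \delta|w_i| - \varepsilon,\; w_i + \delta|w_i| + \varepsilon\,]$.
Tighter thresholds mean more binaries forced to 1 and a harder MILP;
looser thresholds wash out the on/off signal. Both are exposed in
`room_parameters()` and `ba_config()`.

The indicator constraints use per-reaction big-M coefficients
$(v^{\max}_i - w^u_i)$ and $(v^{\min}_i - w^l_i)$ taken from the model's
own (post-knockout) bounds rather than a single global constant: the
relaxation is tighter and no magic number needs tuning.

### Fitness: which production number?

A ROOM optimum is itself degenerate: any vertex of the optimal face is a
legitimate flux vector, and its target flux can vary by
$O(\delta \cdot |w|)$ — with the default 3 % threshold, a mutant
producing ~5 mmol gDW⁻¹ hr⁻¹ can legally report anywhere within
±0.15 of it. A fitness read directly off the MILP vertex would therefore
be solver-dependent, and could never agree with an independent evaluator
to the 0.001 tolerance the validation step demands.

The package resolves this by separating the two roles a candidate
evaluation plays:

* **Viability** is judged by ROOM: the solve must be optimal, the
  predicted growth must exceed 0.1 h⁻¹, and the predicted production
  must not fall below −10⁻³ mmol gDW⁻¹ hr⁻¹.
* **Fitness** of a viable candidate is the *growth-coupled minimum
  production*: biomass is maximized under the knockout, then fixed, and
  the minimum attainable target flux is computed
  (`production_at_optimal_growth()`). This is the pessimistic,
  deterministic number a strain designer actually cares about — the
  production the mutant cannot avoid while growing optimally — and the
  same quantity the post-hoc validation recomputes.

ROOM's own flux read-outs (growth and target flux at the MILP vertex)
are retained in every `room_result` and in the evaluation log, so both
definitions remain inspectable side by side.

### Validation

A final knockout list is *valid* when the production rate the search
reported agrees with an independent re-evaluation within an absolute
0.001 mmol gDW⁻¹ hr⁻¹ (`validate_knockout()`). The tolerance is read as
absolute, not relative: production rates of interest are $O(1)$–$O(10)$,
where a relative reading would change little, and an absolute threshold
is the natural reading of a fixed numeric cutoff. The evaluator is the
fixed-knockout envelope computation above — a deliberate, deterministic
stand-in for a full bilevel knockout-design program, of which only the
resulting production number is needed for this bookkeeping.

## The search

`ba_config()` carries the published parameterization as defaults:
`n = 30` scouts, `m = 20` selected sites, `e = 2` elite sites, `nep = 4`
recruits per elite site, `nsp = 8` per other selected site, `ngh = 1`,
initialization pool `dimension = 2000`, `imax = 50` iterations. Three
points in that table need interpretation, and the package's choices are:

* **Initialization pool.** The population is described both as $n = 30$
  bees and as a 2000-column random matrix. We read the 2000 as an
  oversampled pool: `dimension` random genotypes are generated, repaired
  and deduplicated, and the first `n` distinct ones become the scouts.
  Both printed numbers keep a coherent meaning.
* **Repair.** An unconstrained random binary vector over the reaction
  list would knock out half the network, while the benchmark protocol
  reports 1–5 knockouts. Every genotype is therefore repaired by
  re-enabling uniformly chosen knocked-out positions until at most
  `max_knockout` zeros remain. Repair draws from the run's single RNG
  stream, so it is seeded and reproducible.
* **Site selection.** The description of selection is contradictory
  (random picking in one sentence, fitness sorting in the procedure
  itself). We follow the canonical Bees Algorithm and the procedural
  reading: sort by fitness, take the top `m`, the best `e` of which are
  elite. Note also that the published recruit counts give elite sites
  *fewer* recruits (4) than ordinary selected sites (8); the values are
  kept verbatim rather than swapped, and both are configurable.

The neighbourhood of a binary genotype is a Hamming ball: each recruit
flips up to `ngh` uniformly chosen bits, is repaired, and is scored; the
site representative is the best of the site and its recruits. The
geometric "patch size" of the classic Bees Algorithm has no direct
analogue for bit strings, which makes the Hamming radius the natural
translation.

Ties between candidates are broken by higher growth, then by the
lexicographically smallest sorted knockout set. The rule is invented —
no tie-break is published — purely to make runs deterministic; it never
changes which fitness value wins.

Each iteration re-fills the colony with the `m` site representatives
plus `n − m` fresh random scouts, the canonical reading of
"representatives from each patch plus other scouts". Elitism is
implicit: representatives never lose to their own site, so the global
best fitness trace is non-decreasing. Every distinct knockout set is
solved at most once per run (memoization on the canonical sorted set);
the evaluation log records each actual MILP call.

`measure_performance()` wraps the repeated-run protocol: for each
maximum knockout size it reruns the optimizer with distinct derived
seeds and tabulates mean and standard deviation of the best mutant's
growth rate and the fractions of runs with an optimal solver status and
a validated final list.

## Gene level and reaction level

Bees encode genotypes over *reactions* (the natural unit for the flux
model), while deletions in the laboratory are *genes*. The package
exposes both entry points: `reactions_disabled_by(model, genes)`
evaluates each reaction's GPR rule with the deleted genes set false
(AND = enzyme complex, OR = isozymes) and returns the disabled reaction
set; reports annotate each knockout list with the genes associated with
its reactions. GPR evaluation is pure boolean logic and monotone:
deleting more genes can only disable more reactions.

## The synthetic fixtures

`make_toy_network()` generates the models the tests and the acceptance
script run on: a substrate exchange with uptake 10 mmol gDW⁻¹ hr⁻¹
(the conventional glucose-uptake setting of aerobic minimal-medium
simulations), a catabolic chain whose first step yields an energy
cofactor, a two-step product route, `branches` single-step overflow
drains, and a biomass reaction consuming intermediate and cofactor in a
10:20 ratio. The ratio is chosen so that maximal growth (0.5 h⁻¹ at
uptake 10 — a realistic aerobic growth rate) consumes only half of the
carbon, and the rest must overflow: the wild type grows but guarantees
zero production, a single-drain network has a unique optimal single
knockout, and a two-drain network requires a double knockout — all
verifiable by exhaustive enumeration (`brute_force_optimum()`,
`brute_force_table()`), which the generator attaches as an oracle table.

What the fixtures emulate: growth-coupling through a shared precursor
and energy balance, competing drains, isozymes and enzyme complexes in
the GPR layer, the COBRA sign convention for exchanges. What they do
not: network degeneracy at genome scale (thousands of alternate optima),
cofactor swapping between redox carriers, regulatory effects, and MILP
instances large enough to stress a solver. Passing tests on fixtures
therefore certify the algorithmic machinery — not predictive accuracy on
a real reconstruction, which depends entirely on the loaded model and
medium.

## Numerical choices

* LPs are solved by a dense two-phase simplex with Bland's rule —
  guaranteed finite termination on the heavily degenerate LPs metabolic
  stoichiometry produces, at sizes (tens of rows) where a dense tableau
  is exact and fast. Pivot tolerance 1e−9; feasibility assertions in
  tests use 1e−6. The backend is cross-checked against an independent
  LP solver on randomized problems in the test suite.
* Non-finite bounds are clamped to ±10⁶ (the conventional "unbounded"
  magnitude in COBRA files is ±1000, occasionally 999999).
* The ROOM MILP is solved by depth-first branch and bound on the
  fractional indicator furthest from integrality, warm-started with an
  incumbent built from the mutant's FBA solution (indicators set
  wherever that solution leaves the significance window). Integrality
  tolerance 1e−6; a per-solve wall-clock limit (default 60 s) returns
  the best incumbent with a flagged status instead of blocking a run.
* Knockouts clamp both flux bounds to zero; columns are never deleted,
  so genotype positions stay aligned with the reaction list.
* Infeasible or non-optimal evaluations score −Inf and are discarded;
  an entire run without a viable candidate returns an explicitly flagged
  empty report rather than an error.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run on 7–8-reaction fixtures:
ROOM is verified against exhaustive enumeration over all binary change
patterns on 20 generated fixtures, search results against brute force
over all knockout sets of size ≤ 2–3, and the repeated-run protocol over
10 seeded runs at `max_knockout = 1`, with a reduced colony
(`n = 10, m = 6, dimension = 200`) where many runs are needed. The full
published colony (30/20/2000, 50 iterations) is exercised on the
two-drain fixture in the acceptance script; on models this small the
memoized search visits every reachable knockout set, so its optimum is
exact, not merely probable.

## Limitations

* The built-in simplex and branch-and-bound target desk-scale models;
  a genome-scale ROOM MILP (thousands of binaries) needs an industrial
  solver behind the same interface.
* MOMA-style quadratic adjustment is not implemented; ROOM is the only
  phenotype predictor.
* The validation evaluator is the fixed-knockout production envelope,
  not a bilevel design program: it verifies production numbers, it does
  not propose competing knockout sets.
* `measure_performance()` at genome scale is cluster work; the shipped
  protocol is the scaled-down desk version.
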