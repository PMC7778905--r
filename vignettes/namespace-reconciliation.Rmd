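---
title: "Reconciling metabolite and reaction namespaces, and verifying that models survive it"
author: "xrefforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling metabolite and reaction namespaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrefforge)
```

## The problem

Genome-scale metabolic networks (GSMNs) and the biochemical databases they
draw on name the same small molecules in incompatible ways: one resource
says `CHEBI:15377`, another `cpd00001`, a model says `M_h2o_c`, and many
legacy models use bare symbols with no structure attached at all.  A
unified namespace assigns one identifier (here `MNXM<n>`) to each *set* of
external entries believed to be the same biochemical entity, selects one
member as the reference, and rewrites reactions accordingly.  Because
merging metabolites merges reactions, reconciliation can change what a
model is able to do — so the package also classifies every reaction's
flux-carrying status before and after mapping and checks that the status
profile is conserved.

This vignette explains the models and procedures the package implements,
the tunable parameters and their defaults, the design decisions taken
where more than one reading was defensible, and what the synthetic
fixtures do and do not establish about real data.

## Structure keys: which InChI layers count

A standard InChI is a layered encoding: Hill formula, connectivity
(`/c`), hydrogens (`/h`), charge (`/q`), protonation (`/p`),
stereodescriptors (`/b /t /m /s`) and isotopes (`/i...`).  Two database
entries that differ only in protonation state, total charge or isotopic
labelling are conventionally the same metabolite for modelling purposes,
so the merge key (`structureKey()`) is built from:

* the Hill formula with the hydrogen count elided (protonation changes
  only H count and charge), multi-component formulas keyed componentwise
  and sorted so salt order cannot break equality;
* the connectivity layer verbatim;
* the stereodescriptor layers, kept by default.

`/p`, `/q` and `/i` never enter the default key.  Tautomers are handled
by standard-InChI canonicalization alone (mobile-hydrogen groups are
already folded into the `/h` layer); no extra tautomer enumeration is
attempted, and structures are consumed as precomputed InChI strings —
no SMILES conversion, no structure drawing, no R-group interpretation.

Stereochemistry gets special treatment because real databases disagree
on it: frequently one resource fully specifies a stereocenter while
another omits it.  `similarStructures()` therefore distinguishes
`IDENTICAL` (skeleton and stereo equal), `STEREO_RELAXED` (equal
skeletons, at least one side without stereodescriptors) and `DIFFERENT`.
Two *conflicting* fully specified stereo strings (L- vs D-alanine) are
`DIFFERENT` and are never merged automatically — they are recorded as
`STEREO_AMBIGUITY` conflicts for curation instead.  This is the
package's explicit, conservative definition of "similar structure";
nothing fuzzier is ever used.

## Three lines of evidence, run successively

`reconcileSources()` grows a union–find partition over all source
metabolites in three strictly ordered passes, each run to a fixed point
before the next starts:

1. **Identical structures.**  Metabolites with equal default-policy keys
   merge.  Names alone never merge anything in this pass; metabolites
   without structures stay singletons.
2. **Similar structures in reaction context.**  When two reactions from
   different sources are cross-referenced as equivalent, both equations
   are rewritten with current class ids.  If they agree except for
   exactly one unmatched term on the left and/or one on the right — with
   equal coefficients and compartments — those term pairs become merge
   candidates; a candidate merges if its keys are `STEREO_RELAXED`.
   Both relative orientations are tried when either reaction is
   bidirectional, and a unique consistent orientation is required;
   reactions with two or more unmatched terms on one side contribute
   nothing.  This deliberately conservative alignment is what keeps
   false merges out at the cost of some recall (see the fixtures
   section).
3. **Structure and symbol in reaction context.**  A candidate pair
   merges if at least one member has no structure and the two share a
   normalized name (case folded, all punctuation/whitespace runs
   collapsed; exact match only).  A pair in which *both* members carry
   structures is never merged by names: structure evidence outranks
   symbols.  The package treats this as the resolution of a genuinely
   open design point and flags it here rather than hiding it.

Imported metabolite-to-metabolite cross-references are read (the source
TSVs may carry an `xrefs` column) but **never consulted**: only reaction
cross-references provide context.  This isolates the reconciliation from
error propagation in external links, and the test suite enforces it by
injecting deliberately wrong metabolite xrefs and asserting bit-identical
output.

Conflicts of the form "two members of one merge set sit on opposite
sides of a reaction" (`SAME_REACTION_SIDES`) are detected automatically.
They are *not* errors per se — an acid/base or tautomer pair may validly
merge, emptying the reaction — so by default they are reported `PENDING`
and the merge stands.  `strict = TRUE` reverses this: such unions are
rejected and logged `REJECTED`.

## References and identifiers

Within each merge set the reference is chosen as: (1) a ChEBI member
whose id occurs in Rhea reactions; (2) the earliest-priority prefix with
a structure; (3) the earliest-priority member outright — ties always
broken by lexicographic `(prefix, local id)`.  The default priority
order (`defaultPriority()`) starts `chebi, metacycM, keggC, ...` and is
configurable.

Identifiers are assigned deterministically from content, not insertion
order: sets are sorted by reference and numbered `MNXM2, MNXM3, ...`
without zero padding, so reruns on identical input are byte-identical
and diffs across runs are meaningful.  The historical numbering of any
real distribution is deliberately not reproduced.  `MNXM1` (the
equation-balancing proton) and `MNXM01` (the transported proton of the
proton motive force) are pre-allocated and never reassigned.

## Reaction space

Rewriting an equation substitutes namespace ids, combines like terms,
cancels the common part of any metabolite present on both sides and may
leave an *empty* equation — which is precisely what happens to an
acid/base interconversion after its two sides merge, and such reactions
disappear from mapped models.

Balance handling is deliberately narrow.  `balanceCheck()` computes
exact element and charge deltas; only a `PROTON_ONLY` imbalance (H delta
equal to charge delta) is ever repaired, by adding `MNXM1` to the
deficient side.  Anything else stays `UNBALANCED` or `UNKNOWN` (missing
formula or charge) — a non-proton imbalance is never silently "fixed".
Protons that cross compartments are relabelled `MNXM01` by a min-rule on
opposite-side coefficients; leftover protons remain `MNXM1`.

Reactions deduplicate by a canonical key: terms sorted within sides,
coefficients rescaled to the smallest coprime integers (exact rational
arithmetic throughout — coefficients are stored as numerator/denominator
pairs, never floats, so keys are bit-stable), and the orientation chosen
so the lexicographically smaller side comes first.  Direction is *not*
part of the key; members that disagree on direction yield a
`BIDIRECTIONAL` unified reaction (the permissive choice, logged as such).
Whether fractional biomass-style coefficients ought to be rescaled
before keying is unsettled in the field; this package's
smallest-coprime-integer normalization is its own convention.  Reaction
references prefer a Rhea-prefixed member, then the metabolite priority
order.

## Mapping a model

`readSbmlModel()` accepts SBML level 2 and level 3 (+FBC v2) through a
small purpose-built reader (no libSBML binding is required): bounds come
from FBC parameters, level-2 kinetic-law `LOWER_BOUND`/`UPPER_BOUND`
parameters, or the `reversible` flag with big-M defaults; annotations
are parsed from identifiers.org URIs.  Mapped models are always written
as level 3 + FBC v2.

`mapModel()` maps species with precedence *annotation > exact id
cross-reference > exact normalized name* — first match wins, and a
disagreement between annotation and name is logged at `WARNING` because
annotations are machine-curated while names are free text.  Unmapped
species keep their model-local ids.  Reactions are rewritten inside the
model's own compartments; outcomes are `ONE_TO_ONE`, `MERGED` (canonical
keys collide after mapping), `EMPTIED`, or `UNMAPPED_PARTICIPANT`, and
the four outcome classes always partition the model's reactions.  The
diagnostic taxonomy is this package's own documented surface; merged
reactions are reported but all kept, so stoichiometry is never altered
silently.

## Flux status A/a/b/B

Over the steady-state polytope \(\{v : S v = 0,\ lb \le v \le ub\}\) a
reaction's status is the first regime in which it can carry flux
(`max v_r >` tol or `min v_r < -` tol):

| status | regime |
|---|---|
| `A` | original bounds |
| `a` | all boundary (exchange) reactions made bidirectional |
| `b` | every reaction made bidirectional |
| `B` | never — blocked by topology (e.g. a dead-end metabolite) |

A boundary reaction is one with an empty equation side or touching a
boundary-flagged species — SBML encodes both idioms.  The regimes relax
bounds monotonically, so a status can only improve along the ladder;
this is property-tested.  Each classification needs at most six small
LPs, evaluated lazily.

Three numerical choices matter and are all configurable: `tol = 1e-6`
(flux below tol is "zero"), `bigM = 1000` (stands in for unbounded
fluxes, the common COBRA convention), and bounds that exclude zero
(forced maintenance fluxes) are clamped to include zero with a warning,
because the status definition presumes \(v = 0\) is feasible.  Whether a
forced-flux reaction should instead count as `A` outright is left
undecided by the status definition; the clamp is this package's
documented choice, applied loudly, never silently.

### The LP engine and its oracles

The LPs are solved by a dense bounded-variable primal simplex written
for this package (`solveFluxLP()`), using Bland's rule so the heavily
degenerate flux polytopes cannot cycle.  Its answers are cross-checked
by two independent exact methods in rational arithmetic:

* `nullspaceFluxTest()` — appending the unit row \(e_r\) to \(S\) raises
  the rank iff some nullspace vector has \(v_r \ne 0\); this decides the
  fully relaxed regime exactly for any positive bound magnitude.
* `exactFluxRange()` — enumeration of the polytope vertices (every
  vertex fixes \(n - \mathrm{rank}(S)\) coordinates at a bound), with
  fraction-free eliminations for rank and exact rational solves.  This
  is exponential and intended for networks of ≤ 8 reactions, which is
  what the test fixtures use.

The test suite demands bit-exact agreement between the LP route and the
exact route on the whole fixture catalogue and on thousands of random
matrices; the two routes share no code.

### Two facts about status motifs worth recording

The fixture generator builds models from motifs whose statuses are
provable, and two non-obvious facts shaped it:

1. **An irreversible 2-cycle is `A`, not `b`.**  With \(A \to B\) and
   \(B \to A\) both irreversible, \(v_1 = v_2 \ge 0\) satisfies
   \(Sv = 0\), so the loop carries flux under the original bounds.
   Plain steady-state analysis admits internal loop flux; only a
   thermodynamic loop law (out of scope) would forbid it.  The genuine
   `b` motif is a cycle with one edge *reversed* (two parallel
   same-direction reactions in the smallest case): blocked until every
   bound is relaxed.
2. **Statuses `a` and `b` cannot occur alone.**  If reaction \(r\) is
   blocked in one regime but feasible in the next, its witness flux must
   drive some other reaction against a bound that only the same
   relaxation lifted; a short cone argument shows that reaction has the
   same status as \(r\).  So `a` and `b` reactions always come in groups
   of two or more, and `generateModel()` rejects block requests with a
   single `a` or `b` as infeasible rather than emitting a model whose
   ground truth would be wrong.

### Conservation checking

`conservationCheck()` pairs the statuses of one-to-one mapped reactions
before and after mapping and reports every change.  A bijective species
mapping cannot change any status (the stoichiometric matrices are
isomorphic — this "theorem case" is tested), but merging metabolites
can, and the change need not involve the merged species: the suite
constructs a network where merging two metabolites closes a flow loop
and flips an untouched downstream reaction from `B` to `A`.  Exactly
this kind of indirect effect is why status conservation is worth
checking after every reconciliation change.

## What the synthetic fixtures emulate — and what they don't

`generateSources()` emulates the statistical structure of overlapping
biochemical namespaces: each true compound appears in several sources
under different local ids and name spellings; per copy, its structure is
dropped with probability 0.3 (keeping name and formula), protonated
differently with probability 0.5, and stereo-erased with probability
0.15; shared reactions are written per source and cross-referenced with
density 0.9, with at least two cross-reference edges per shared reaction
and every compound placed in at least two coverage-compatible reactions.
These defaults are the study conditions for the recovery benchmark: on
20 seeds the three-pass reconciliation achieves aggregate merged-pair
precision of 100% and recall above 95% against the generator's ground
truth.  The residual recall gap is structural, not random: when two
structure-dropped copies share one side of the only reactions linking
them, the one-unmatched-term rule can never isolate either pair, and the
conservative alignment (correctly) refuses to guess.

Synthetic InChIs come from a restricted valid grammar — chain skeletons
over C/N/O with optional stereo and protonation layers — so the layer
machinery is fully exercised without any cheminformatics dependency.
What passing these tests shows is that the evidence logic, conflict
detection and bookkeeping are correct under controlled perturbations.
What it cannot show: robustness to real-world name synonymy (the
generator's names are unique per compound), R-group and polymer
structures, inconsistent formulas, or the scale of real resources
(millions of entries).  External validation against a real model and a
real distribution is wired into the acceptance test but requires
downloads and is not part of the desk-scale suite.

Model fixtures use the motif catalogue above; `A`- and `a`-motifs are
wired to a hub metabolite (whose exchange is counted among the `A`
reactions) while `b`/`B` motifs stay as separate components, because any
wiring of those through a hub either changes their statuses or adds
reactions outside the requested blocks.  All planted ranges are either
exactly zero or at least one in magnitude, so no classification sits
near the tolerance; statuses are stable across `tol` from 1e-9 to 1e-5,
and the suite checks this.

## Problem sizes

The default benchmark uses 40 true compounds across 3 sources (about
100 source metabolites) with 25 shared reactions, 20 generator seeds for
the recovery benchmark, fixture networks of at most 8 reactions for the
exact-oracle comparisons, 1000 random 6×8 matrices for the
nullspace-versus-LP cross-check and 100 random motif models for the
property suites.  These sizes keep every oracle exact and the full suite
fast while covering all code paths; the pipeline itself has no intrinsic
size limit, though the bundled dense simplex is written for small
fixture-scale LPs, not for genome-scale flux variability (use it to
verify logic, not to race a commercial solver).

## Known limitations

* Name evidence is exact-match after normalization; synonym lists are
  honoured only if provided in the source files' `names` column.
* Compartment labels must match exactly across a merged reaction group;
  no compartment-name unification is attempted.
* The SBML subset covers core + FBC v2 constructs used by
  constraint-based models; kinetic models round-trip only their
  stoichiometric skeleton.
* Gene–protein–reaction associations are untouched by mapping.
* Thermodynamic direction inference, Gibbs-energy estimates and loop-law
  filtering are out of scope.
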