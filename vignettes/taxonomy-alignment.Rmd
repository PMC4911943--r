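---
title: "Aligning taxonomic concept hierarchies with RCC-5: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning taxonomic concept hierarchies with RCC-5: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxalign)
```

This vignette is the package's own account of its model, its algorithms,
and the design decisions behind them — what is computed, under which
assumptions, and what the shipped tests do and do not establish.

## The model

A **taxonomic concept** is a name as used by one particular treatment
("name sec. author"), read as a set-like circumscription of organisms. A
**taxonomy** here is a rooted forest of concepts connected by parent/child
(*is_a*) edges; multiple roots are legal and are treated as mutually
exclusive. An **articulation** asserts one of the five RCC-5 relations on
nonempty sets between one concept in each taxonomy — congruence `==`,
proper inclusion `>`, inverse proper inclusion `<`, overlap `><`,
exclusion `!` — or a disjunction of them to express uncertainty. By
convention the later treatment (T2) stands on the left of every
articulation and of every output row.

Three global constraints close the model:

* **nonemptiness** — no concept is an empty circumscription;
* **sibling disjointness** — children of one parent do not overlap;
* **coverage** — a parent is exactly the union of its children. Coverage
  may be switched off per concept (a `nocoverage` directive), which is the
  package's minimal accommodation of intensionally circumscribed parents
  that may hold more than their listed children; no further feature
  semantics is attempted.

A **possible world** is an assignment of one base relation to every
cross-taxonomy concept pair that is realized by actual sets satisfying all
of the above. The **MIR** (Maximally Informative Relations) table assigns
to each pair the set of relations realized in at least one world; it has
exactly |T2| × |T1| cells, and a cell with more than one relation marks a
genuine ambiguity of the input, not a failure of inference.

## The encoding: candidate Euler regions

The reasoner grounds the model in **candidate regions**: pairs *(d2, d1)*
where *d2* is an *eligible* concept of T2 or NONE, *d1* likewise for T1,
and not both are NONE. A concept is eligible as "deepest containing
concept" iff it has no children or its coverage flag is off — under
coverage, an element of a parent is always an element of some child, so
covered parents never appear as deepest nodes. With `e2` and `e1` eligible
concepts there are `(e2 + 1)(e1 + 1) - 1` regions.

An interpretation is simply the set of occupied regions; a concept's
extension is the union of occupied regions whose deepest node lies
at-or-below it. Sibling disjointness and within-taxonomy nesting are then
true *by construction* of the signatures, which is why the package rejects
`sibling_disjointness = FALSE` rather than pretending to honor it. What
remains to be constrained:

* nonemptiness: per concept, a positive clause "at least one region
  at-or-below me is occupied";
* an articulation on pair (x, y): with I/L/R the regions inside x∩y, x\\y,
  y\\x, each base relation is equivalent to a **witness pattern** —
  `==`: L, R empty; `>`: R empty, L occupied; `<`: L empty, R occupied;
  `><`: I, L, R occupied; `!`: I empty. (The e_int requirements of
  `==`/`>`/`<` follow from nonemptiness once the off-sets are applied.)

For a fixed choice of one base relation per articulation the system is
**monotone**: a set of regions forced empty, plus positive clauses. Such a
system is satisfiable iff every clause retains an allowed region — the
maximal model, occupying everything not forced off, witnesses it. This is
the package's consistency decision: a closure plus a scan, no search at
all for disjunction-free inputs. Disjunctive articulations are handled by
branching over their disjuncts (they are rare in practice; the published
alignments contain none).

## World enumeration and MIR

Worlds are identified by their induced relation maps, not by occupancies —
many occupancies realize the same map, and what is counted scientifically
is alignments, not models. Enumeration branches, in canonical concept
order, on the first pair admitting more than one realizable relation
(realizability of a relation is one monotone satisfiability check of its
witness pattern); when every pair is determined, the branch contributes
exactly one world. A state in which every allowed region is the sole
survivor of some clause has a unique model and hence a unique world — this
fast path is what keeps fully articulated alignments with hundreds of
concepts (where the relation map alone has >10^5 entries) at a few seconds
on one CPU.

`enumerate_worlds()` stops at a cap (default `world_cap = 256`).
`compute_mir()` uses the world union when enumeration exhausts; otherwise
it falls back to one satisfiability query per pair and candidate relation
(5 · |T2| · |T1| monotone checks), so the MIR is exact even when the world
set is truncated. Both routes are asserted to agree in the test suite.
Enumeration is deterministic — branching follows the fixed concept and
relation order, and no randomness is involved anywhere in the reasoner —
so repeated runs produce byte-identical outputs.

Within-taxonomy pairs are *not* part of the MIR (the product law counts
cross pairs only); they are fixed by the hierarchy and coverage and exposed
by `within_taxonomy_relation()`: ancestor `>` descendant, `==` along
monotypic coverage chains, `!` otherwise.

Inconsistent inputs are handled by `diagnose()`: deletion-based
minimization over the articulations with the taxonomy structure held
fixed, returning a subset that is unsatisfiable while every proper subset
is satisfiable. Minimality is of the subset-minimal kind; when several
minimal cores exist, which one is returned depends on articulation order.

## Verification strategy

The package carries its own referee. `oracle_worlds()`/`oracle_mir()`
enumerate all `2^k - 1` occupancy subsets of the candidate regions
(refusing instances beyond `max_regions = 20`), evaluate every articulation
on the actual extension sets — the same set semantics as
`rcc5_classify()`, independent of the witness-pattern machinery — and
deduplicate induced maps. The central correctness property of the
repository is exact agreement of reasoner and oracle (consistency verdict,
world set, and MIR) on hundreds of seeded random problems with up to three
leaves per taxonomy; the worked example (39 regions) lies deliberately
above oracle range and is instead pinned to its published counts.

The RCC-5 composition table shipped in `rcc5_compose()` is likewise
derived, not transcribed: `derive_composition_table(n)` brute-forces all
subset triples of an `n`-element universe. The table is stable from
universe size 5 upward; size 6 is shipped and the suite checks
`derive(6) = derive(7) = shipped`. (One consequence worth noting: `>`
composed with `<` cannot yield `!`, because the two outer sets share the
middle one.)

## Metrics

With the MIR in hand, `metrics_report()` assembles the quantitative
analyses. Relation **tallies** count singleton cells per relation,
reporting disjunctive cells separately as ambiguous; tallies plus the
ambiguous count always sum to |T2| × |T1|. The **information expression
ratio** is MIR cells divided by input articulations. **Relative
congruence** is 100 × (congruent cells) / (concepts of the concept-poorer
taxonomy); it may exceed 100 when the richer taxonomy holds redundant
monotypic-chain concepts, and the implementation follows the formula even
where a printed table would clip it at 100. The per-rank **name:meaning
table** classifies same-rank pairs as `==:=`, `==:!=`, `>:=`, `<:=`,
`><:=` ("same name" is exact string identity of the name token, so a
re-combined epithet counts as a different name); pairs that are neither
same-named nor congruent are not counted, ambiguous cells are excluded
unless a world is chosen, and the impossible-for-Code-compliant-inputs
`!:=` category is checked and warned about. The **reliability ratio**
normalizes reliable (`==:=`) versus unreliable (the other four categories)
counts with the smaller side printed as 1.

Rounding throughout is to one decimal, half away from zero, matching
printed-table style; rank labels are compared case-insensitively after
trimming, and only ranks present in both taxonomies are tabulated. ASCII
`==:!=` is used for the "congruent, different names" category so that CSV
headers and column names stay locale-proof.

## Merge graphs

`build_merge()` turns a single alignment (an all-singleton MIR, or one
chosen world) into the reduced containment graph: concepts grouped into
congruence classes (cross-pair `==` closure plus monotypic coverage
chains), containment edges from `>`/`<` cells and parenthood with a
transitive reduction, and `><` cells as dashed overlap edges.
`combined_concepts()` resolves each overlap edge (A, B) into Euler
subregion nodes A\*B, A\\B, B\\A; since an overlap relation asserts all
three subregions nonempty, all three nodes are added per edge — the
emptiness rule in the code is general but cannot fire for graphs built
from a world. `to_dot()` emits deterministic GraphViz text with the
conventional styling (green boxes for T2-only, yellow octagons for
T1-only, gray rounded boxes for congruent classes, dashed blue overlap);
shapes and colors are overridable through a style table, and rendering to
PDF/SVG is out of scope. Subregion emptiness and world choice follow the
displayed-alignment convention: one world at a time (`--world` in the
CLI, default index 0).

## Synthetic data: what it emulates, what it does not

Three generators define the study conditions:

* `fixture_fig1()` — the hard-coded mouse-lemur worked example: 11 + 4
  concepts, 9 articulations (three `<` reassessment narrowings, four `!`
  acquisitions, two `==`). Its concept lists are a reconstruction from the
  published figure of that alignment; the reconstruction is validated by
  the printed outcomes it must and does reproduce (consistency, exactly 2
  worlds, 44 MIR cells, one `{> ><}` cell, monotypic congruence, genus
  overlap).
* `make_sized_pair(n2, n1, a)` — exact-size instances for the MIR product
  law. T1 is a root-plus-clades tree; T2 clones it and attaches `n2 - n1`
  acquisition leaves. Articulations follow the species-level-plus-root
  recipe observed to suffice in practice: every shared leaf `==`, every
  new leaf `!` the T1 root, root `>` root, padded to exactly `a`
  articulations with logically implied statements (clade congruences,
  leaf exclusions) that provably cannot change the world set. The T1 leaf
  count is chosen so the recipe hits `a` without padding when possible
  (for 483/317/402 that is 235 leaves and no padding). Every instance is
  consistent with exactly one world.
* `generate_evolved_pair()` — seeded classification-change scenarios:
  k-way reassessment splits (children `<` the old leaf; whether the union
  of children exhausts it is deliberately left open), acquisitions (`!`
  the T1 root — the strongest exclusion the articulation conventions use;
  exclusion against a nearer parent would be a weaker variant),
  lumps (the merged T2 leaf `>` each constituent), renames (`==` under a
  new name). The root articulation is emitted only when unambiguous: `>`
  with acquisitions present, `==` when nothing changes extensions, none
  when only splits/lumps occur (pinning the root there would erase the
  split-slack ambiguity).

The expected world count of an evolved pair is `2^f`, where `f` counts the
free regions the recipe leaves neither forced nor excluded: one per split
(may the old concept exceed its narrowed children?) and one per lump (may
the merged concept exceed the lumped pair?) — the latter killed by a root
`==`, the former by a root `>` — plus one per lump × split pair, since no
articulation relates a lumped concept to a split target. The test suite
verifies this count, and the full oracle MIR, across the scenario grid.

What the generators do **not** emulate: real classifications have deep
heterogeneous rank structures, partial articulation coverage (concepts
never mentioned by any articulation), genuinely intensional parents, and
editorial irregularities; synthetic instances are regular by construction.
Passing the suite therefore shows the reasoner is exact for the encoded
semantics and recipes — it does not show that any particular published
articulation set is taxonomically correct, nor does it exercise dialect
quirks of other tools' input files.

## Numerical and interface choices

* Exclusion serializes as `!`; `|` is accepted on input only, since it
  collides with shell and CSV conventions.
* Relation sets serialize in the fixed order `==`, `>`, `<`, `><`, `!`,
  brace-delimited when disjunctive (`"{> ><}"`).
* `world_cap` default 256; the MIR stays exact past the cap via the
  per-pair fallback.
* The oracle's `max_regions = 20` bounds its subset enumeration at about
  10^6 occupancies, keeping it honest and fast.
* Degenerate inputs: single-concept taxonomies are legal (coverage is
  vacuous); an empty articulation set is legal (every relation is then
  realizable for every pair); an empty relation set in a statement is a
  parse error, as are duplicate concepts, unknown references, and cycles —
  each reported with its line number.
* Problem sizes in the shipped tests are the package's choices for a
  thorough-but-brisk default run: 200 seeded oracle-agreement instances at
  up to 3 leaves per side, the change-scenario grid at 8 T1 leaves, and
  one full 483 × 317 product-law instance.

## Known limitations

* Exactly two taxonomies per problem; aggregate views over multiple
  alignments and decision-tree disambiguation of ambiguous inputs are out
  of scope.
* No import of other alignment toolkits' native file dialects; the
  line-oriented dialect documented in `parse_alignment()` is this
  package's own.
* Diagnosis returns one minimal core, not all of them, and suggests no
  repair ranking.
* The name:meaning analysis is descriptive; no statistical inference is
  attached to the ratios.
* Figure layout is the renderer's business: DOT text is deterministic,
  published-figure geometry is not reproduced.
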