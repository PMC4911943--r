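# taxalign

Logic-based alignment of taxonomic concept hierarchies with RCC-5.

## The problem

Classifications change between treatments: species get split, lumped,
renamed, and newly discovered material is added. Because the Linnaean name
system tracks these changes imperfectly, the *same name* can point to
*different circumscriptions* in two editions of a standard (and congruent
circumscriptions can carry different names). `taxalign` is for systematists
and biodiversity informaticians who need to resolve such name:meaning
dissociations precisely, at the level of individual *taxonomic concepts*
("name sec. author") rather than bare names.

Each classification is modeled as a hierarchy of concepts connected by
parent/child (*is_a*) edges. An expert articulates selected concept pairs
across the two hierarchies with the five RCC-5 relations on nonempty
regions:

| symbol | meaning |
|--------|------------------------------------------|
| `==`   | congruence                               |
| `>`    | proper inclusion (left includes right)   |
| `<`    | inverse proper inclusion                 |
| `><`   | overlap                                  |
| `!`    | exclusion (`\|` accepted on input)       |

Uncertainty is a disjunction, e.g. `{== >}`. Three global constraints apply:
every concept is nonempty, siblings are disjoint, and a parent is covered by
the union of its children (relaxable per concept). The reasoner decides
whether taxonomies T1, T2 plus articulations A and constraints C are
jointly consistent, enumerates the **possible worlds** (globally consistent
assignments of one base relation to every cross-taxonomy pair), and derives
the **Maximally Informative Relations (MIR)**: for each of the
|T2| × |T1| concept pairs, the set of relations realized in at least one
world. The MIR is a complete meaning-resolution map; merge graphs and
name-reliability statistics are computed from it.

Internally the package encodes a problem over *candidate Euler regions* —
pairs of deepest containing concepts, one per taxonomy (or none). For a
fixed choice of base relation per articulation the constraint system is
monotone (forced-empty regions plus positive occupancy clauses), so
consistency reduces to a closure computation; disjunctive articulations and
world enumeration branch on top of that, and an independent brute-force
occupancy oracle cross-checks the reasoner exhaustively on small instances.

## Worked example

The shipped fixture reconstructs the mouse-lemur alignment between two
classification editions: the 2005 treatment (genus *Microcebus* with eight
species plus the monotypic genus *Mirza*; 11 concepts) against the 1993
treatment (*Microcebus* with three species; 4 concepts), connected by nine
articulations.

```r
library(taxalign)
p <- fixture_fig1()
check_consistency(p)$consistent
#> [1] TRUE
ew <- enumerate_worlds(p)
length(ew$worlds)
#> [1] 2
mir <- compute_mir(p)
mir
#> <MIR table 2005 x 1993: 44 cells (11 x 4 concepts)>
#>   worlds found: 2 (exhausted); input articulations: 9
#>   == 3  > 1  < 9  >< 1  ! 29  ambiguous 1
mir_cells(mir)["2005.Microcebus", "1993.Microcebus_murinus"]
#> [1] "{> ><}"
expression_ratio(mir)
#> [1] 4.9
```

Nine input articulations expand into 44 inferred relations (4.9-fold
information expression). Exactly one pair stays ambiguous — whether the 1993
*Microcebus murinus* concept exceeds the union of the three narrower 2005
concepts carved from it — which is exactly why there are two possible
worlds. The monotypic *Mirza* is congruent with its only child under
coverage, and both are congruent with the 1993 *Microcebus coquereli*; the
two genus-level *Microcebus* concepts overlap.

The same run from the shell, including DOT merge graphs and metrics CSVs:

```sh
exec/taxalign align --input inst/extdata/microcebus_mirza.txt \
  --ranks inst/extdata/microcebus_mirza_ranks.tsv --out out/
#> 2 worlds
```

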