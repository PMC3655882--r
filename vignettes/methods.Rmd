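---
title: "Methods: pattern matching, rooting and incongruency screening in gene-tree collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pattern matching, rooting and incongruency screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treequery)
```

## The setting

A *collection* couples a reference species tree — a rooted, possibly
multifurcating taxonomy whose every node carries a primary name and
optional synonyms — with many rooted **binary** gene trees, each leaf
mapped to a species leaf of the reference. Binarity of the gene trees is a
hard requirement of the matcher (the species tree may be unresolved).
Name matching is deliberately forgiving: case-insensitive, underscores
equal spaces, whitespace runs collapsed. This absorbs the inconsistent
capitalisation and spacing that real association tables exhibit, at the
price that two names differing only in those respects collide (the parser
rejects such a species tree outright rather than guessing).

Two derived quantities drive everything downstream:

* the **LCA assignment** of a gene node: the deepest species-tree node
  whose leaf set contains every species below the gene node. Assignment
  always uses the *full* species tree: it names a taxonomic group, and
  that name should not depend on which species happen to be sampled.
* the **restricted depth** of a taxon: the species tree is pruned to the
  species present in the gene tree, degree-2 chains are collapsed (a
  collapsed chain is represented by its deepest surviving member, the most
  specific name the gene tree can still witness), and depth is the edge
  count from the restricted root. Only depths are restricted, not
  assignments: depth measures *resolution given the sampled species*.
  With every species present this is the plain root-to-node edge count.

## Pattern matching

Patterns are binary constraint trees written in an extended Newick
syntax. Each node has up to three slash-separated fields — a node
constraint, a path constraint, and (leaves only) the allowed leaf taxa —
plus modifiers `$N` (support at least N), `D`/`S` (event), and `!`
(direct link), accepted both prefix (`!//Homo sapiens`) and postfix
(`)!`) with identical meaning. Taxon fields are `base +add -remove`
expressions evaluated left to right over species sets; subtraction never
adds members, and an expression that empties itself (`A -A`) warns that
it can match nothing.

An internal pattern node *p* with children *p₁, p₂* matches a gene node
*g* when

1. *g*'s support passes `$N` if present (nodes without a stored support
   value fail any `$` constraint — missing evidence is not evidence);
2. *g*'s event equals the required letter if present. Events come from
   explicit `D`/`S` labels in the input when the collection is
   reconciled, otherwise from the species-overlap rule: a node is a
   duplication iff its two children's species sets intersect;
3. *g*'s own LCA assignment falls inside the node-constraint taxon if one
   is given (and, when the constraint carries `+`/`-` modifiers, the
   species below *g* lie inside the evaluated set). The field is accepted
   on internal nodes as well as leaves; published pattern corpora only
   ever populate it on leaves, so treat the internal form as an
   extension;
4. *p₁* and *p₂* match gene nodes *g₁, g₂* lying in two **different**
   child subtrees of *g*. The connection may be indirect — `!` forces
   *gᵢ* to be the child itself — and every leaf hanging off the
   connecting path (the leaves of the child subtree outside the matched
   subtree) must belong to the path-constraint set when one is given.
   This off-path reading is what makes the canonical accept/reject pair
   work: a non-primate branching *between* the matched parent and the
   matched primate leaf is forbidden, while non-primates entirely outside
   the matched parent are irrelevant.

Pattern leaves match gene **leaves** only; "a clade of X" is expressed
with a path constraint, not by matching a leaf to a subtree. The pattern
root may match at any gene node, and two matches are distinct whenever
any pattern node maps to a different gene node — so one tree can
contribute several matches. Collection queries report matching entries in
collection order; both the number of matching trees and the total match
count are reported, since a "number of trees matching" table and a
"number of matches" table differ as soon as families contain paralogs.

The production matcher is a dynamic program over (pattern node, gene
node) pairs with a per-pattern-child aggregation over admissible
descendants; the test suite holds it equal, match set by match set, to a
brute-force enumerator that generates every structurally admissible
assignment and filters it with a predicate transcribed directly from the
four rules above (500 random tree/pattern cases per run, gene trees up to
12 leaves, patterns up to 4 leaves).

## Rooting

For a gene tree with *n* leaves the unrooted topology has 2n−3 edges and
each is a candidate root; each candidate is rescored from scratch (no
incremental updates, which the tests verify by recomputation).

* **Unicity.** uᵢ is the product over species of sequence counts below
  node i; U(T) = Σ ln uᵢ over the n−1 internal nodes. U ≥ 0, U = 0 iff
  the tree is everywhere unicopy, and the root term is rooting-invariant.
  Minimising U concentrates duplications near the root — a parsimony
  argument that needs no reference tree, which matters for prokaryotic
  families where no trusted species tree exists.
* **Taxonomy.** D(T) = Σ dᵢ, the sum of restricted depths of each
  internal node's assignment. Maximising D picks the rooting whose nodes
  carry the most specific taxonomic labels, i.e. the most
  reference-congruent orientation.
* **Cascade.** The combined strategy filters candidates by minimal U,
  then maximal D, then longest root branch, then the first edge in a
  canonical post-order edge numbering. The numbering makes the "any of
  the remaining candidates would do" step reproducible; runs are
  bit-identical across sessions.

Numerical choices: U-candidates within 1e-9 of the minimum are *ex
aequo* (ln-sums of identical integer multisets must tie in intent, and
64-bit floats do not guarantee it bitwise); the root branch length is the
full length of the edge the root splits; missing branch lengths are
treated as 0 at the branch tie-break, with a warning, rather than
disqualifying a candidate.

## Incongruency detection

Scanning a rooted gene tree strictly post-order (leaves first), each node
with a grandfather is tentatively masked. If the grandfather's LCA
assignment over the unmasked leaves changes, the masked subtree is
incongruent: it is pruned, the record is scored, and the scan restarts on
the pruned tree until a full pass fires nothing. Each prune removes at
least one leaf and pruning never goes below two remaining leaves, so
termination is bounded by n−2 prunings. The perturbation index is the
path length between the old and new assignments on the restricted species
tree; restriction always uses the species of the **full** original gene
tree, so indices from successive prunings of one entry stay comparable.
For nested assignments the path length equals the depth difference
d_new − d_old; the path-length form is kept because after restriction the
two assignments need not be nested.

The support filter takes the support attached to the *father* of the
masked subtree — the clade uniting the misplaced clade with its alien
sibling is what asserts the conflict. When the masked subtree is itself
internal, its own clade support must also pass: masking a weakly
supported clade whose leaf-level conflicts were already rejected by the
threshold would otherwise re-report the same weak signal one level up.
Thresholding is `>=`, consistent with the support constraint in patterns;
branches without a support value never pass. Records are classified by
domain — by default the species-tree root's children — comparing the
domain of the pruned clade's own LCA with the domain of the grandfather's
post-masking assignment; either falling on the root itself makes the
record unclassifiable. Rooting is a prerequisite: the CLI roots with the
combined strategy unless `--assume-rooted` is given, because a wrong root
manufactures false incongruencies.

## The synthetic generator

`gen_species_tree` grows a binary taxonomy by uniform sequential leaf
attachment. `gen_gene_tree` starts from a unicopy congruent copy and
layers events: a duplication copies a clade and grafts it as its own
sister (the first duplication copies the whole tree, the ancient-paralogy
case the unicity criterion is designed for); a transfer prune-regrafts a
random leaf onto a branch where the move is *taxonomically visible*
(the future grandfather's assignment changes when the leaf is masked —
an invisible move is undetectable by definition, in this framework).
Defaults are chosen as the cleanest realistic screening scenario:
supports constant at 100 and the detection threshold at 90, matching the
strongly-supported-conflict regime such screens target; branch lengths
exponential with rate 1, the standard neutral choice where only the
longest-branch tie-break consumes them. The generator emits ground truth
(true root split, transferred sequences, duplicated clades) so recovery
is measured, not eyeballed.

What passing these simulations does **not** show: the generator produces
clean events on correct topologies — it does not emulate reconstruction
error, long-branch attraction, incomplete lineage sorting, rate
heterogeneity, or compound overlapping events, which dominate real
collections. Recovery rates on fixtures (true-root containment ≥95%,
single-transfer exact recovery ≥90%, 200 cases each) are upper bounds on
behaviour for real data, and the residual misses are themselves
informative: a transfer into a clade adjacent to the tree root can leave
the detector a choice of two equally valid prunings, and the post-order
rule then prunes a set different from the seeded leaf.

Problem sizes used throughout the suite — species trees of 4–12 leaves
for property tests, 50 for structural checks, 500 matcher cases and 200
simulations per recovery suite — are the package's chosen validation
scale: large enough that every code path (chains collapsed by
restriction, ties at every cascade stage, multi-prune fixpoints) is hit,
small enough that the whole suite stays interactive.

## Known limitations

* Pattern leaves cannot be optional: testing a deep clade requires every
  listed species to be present in a family, so support counts for deep
  nodes understate the signal (no fuzzy patterns).
* The species-overlap event rule over-calls duplications when the true
  history mixes transfers into sampled species; explicit `D`/`S` labels
  from a reconciled collection take precedence when available.
* The collection text format is this package's own documented dialect
  (header species tree, `>NAME` entries, tab-separated association
  lines); byte compatibility with historical collection files of the
  same lineage is not claimed.
* Donor/recipient inference for transfers, reconciliation, and
  database-scale corpora are out of scope.

## Session

```{r}
sessionInfo()
```
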