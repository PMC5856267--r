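---
title: "Gene-order rearrangement distances and parsimonious mitochondrial phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-order rearrangement distances and parsimonious mitochondrial phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Metazoan mitochondrial genomes carry an almost invariant gene set — 13
protein-coding genes and 2 rRNAs, plus tRNAs — on a single circular
chromosome, so what evolves informatively is the *order* and *orientation*
of the genes.  `generearr` models a genome as a signed permutation of gene
labels.  A circular genome of $n$ genes is identified with its $2n$
representations: the $n$ rotations of the written sequence and the $n$
rotations of its reversal-with-negation (reading the circle the other way
around flips both the order and every strand assignment).  A linear genome
has exactly 2 representations.

Three elementary rearrangements connect gene orders:

* **inversion** — a contiguous block $B$ is replaced by $-B$ in place;
* **transposition** — a block detaches and re-inserts between two other
  successive genes;
* **reverse transposition** — the moved block re-inserts reversed.

Gene gains and losses are handled outside the rearrangement model: before a
pairwise comparison both genomes are reduced to their common genes
(`restrict_to_common()`), and the removed genes are reported as gain/loss
annotations rather than steps.  Tandem-duplication–random-loss events are
deliberately outside the model.

The **distance** $d(G, G')$ is the length of a shortest sequence of such
rearrangements transforming $G$ into $G'$.  It is a metric.  A **path** is
the full genome sequence of a scenario; a path of length $k$ is a
*k-path*.

Because of circularity, distinct operation parameters can produce the same
gene order: from $[A\,B\,C]$ the three transpositions (move $A$, move $B$,
move $C$) all yield the single circular order $[B\,A\,C]$, and from
$[A\,B]$ both inversions yield $[-A\,B] = [A\,-B]$.  The engine therefore
enumerates *results*, not parameterisations: a transposition is generated
once per unordered triple of cut junctions, a reverse transposition three
times per triple (one per choice of inverted arc), and an inversion once
per block/complement pair.  Path enumeration additionally deduplicates
children by canonical form, so a path is a sequence of genomes, never an
operation history.

## The search and its two pruning tests

Distances and path sets are computed by depth-first backtracking with
iterative deepening: all $k$-paths are enumerated for $k = \lceil
\mathrm{bp}/3 \rceil, \ldots$ until a depth admits a solution, which makes
the reported distance exact and the enumeration at that depth complete.
Two admissible tests prune the search:

* **Lower bound (HT2).**  One rearrangement changes at most 3 adjacencies,
  so $3\,d(G,G') \ge \mathrm{nb\_breakpoints}(G,G')$; a branch with more
  breakpoints left than $3\times$ the remaining budget is dead.  This test
  is exact and is also used to start the deepening at
  $\lceil \mathrm{bp}/3 \rceil$.
* **Shared blocks (HT1).**  Among minimal paths there is always one that
  never breaks a block shared by the current genome and the target
  (cut-free paths exist).  Since a shared block's internal adjacencies are
  exactly the non-breakpoint junctions, HT1 is implemented as: *cut only at
  breakpoint junctions*.  HT1 can discard some minimal paths (never all),
  so ancestral inference — which needs every minimal scenario — always runs
  with HT1 off.  Distances are unaffected; the test suite asserts
  heuristics-on/off equality exhaustively for $n \le 5$.

The search additionally never revisits the target mid-path (a minimal path
cannot), and orders children by their breakpoint count so that solutions
are found early at the final depth.

A second admissible bound sharpens the pruning for distant circular
genomes.  In double-cut-and-join (DCJ) terms an inversion is one DCJ and a
(reverse) transposition is two, so $k$ rearrangements perform at most $2k$
DCJs, while sorting $X$ into the target takes exactly $n - c$ DCJs, where
$c$ counts the cycles of the adjacency graph of the two genomes.  A branch
with $n - c > 2 \times \text{remaining}$ is therefore dead.  For random
mitochondrial-size pairs $c$ is small and this bound is much tighter than
$\lceil \mathrm{bp}/3 \rceil$, which is what makes exact distances 6–8
routinely affordable; like the breakpoint bound it can only discard
branches that provably contain no solution, a fact the test suite checks
by comparing against the pruning-free search and a breadth-first oracle.

## Tunable parameters

* `k_max` (default **8** rearrangements): the deepest exact search
  attempted; beyond it the result is reported as a failure/lower bound,
  never a guess.  Random mitochondrial-size gene orders essentially never
  exceed distance 8, and distances above 5 are already unreliable (below).
* `ht1`, `ht2` (default on for distances): pruning toggles, exposed mainly
  to let the test suite verify they never change results.
* `dist_threshold = 5`, `frac_threshold = 0.95` in
  `flag_fast_evolving()`: a taxon farther than 5 steps from strictly more
  than 95% of the others is flagged as a fast evolver, because such
  distances are indistinguishable from comparisons of random genomes.
* `max_htus` (default $N + 4$): ceiling on the number of hypothetical
  ancestors tried before the tree search gives up with an explicit error.

## Trees, ancestors and the solution set

A candidate phylogeny is an unrooted tree whose nodes are the $N$ observed
gene orders (OTUs) plus $M$ anonymous hypothetical ancestors (HTUs); each
edge is one rearrangement.  Observed genomes may sit at *internal* nodes —
an extant order can be ancestral.  The axioms are: simple (P1), undirected
(P2), a tree (P3), every inter-OTU path at least as long as the exact
pairwise distance (P4), and user-imposed monophyly constraints relative to
a root taxon (P5).  `enumerate_parsimonious_trees()` searches domains of
increasing size $V = N + M$ and returns *all* axiom-satisfying trees on the
smallest admissible domain, up to isomorphism fixing OTU labels.
Completeness comes from generating every labeled tree (Prüfer sequences)
and collapsing isomorphic duplicates with a color-aware canonical form;
trees with pendant HTUs are dropped because deleting such a node always
leaves a valid smaller tree, so they can never be minimal.  This
generate-and-filter backend is complete at each $V$ by construction; any
other complete backend (e.g. a propositional model generator) could be
swapped in behind the same interface.

Property P6 is checked per tree (`validate_tree_ancestors()`): for every
OTU pair linked through HTUs only, all paths of exactly the tree-path
length are enumerated (HT1 off), and each intermediate HTU collects the
genomes seen at its position.  An HTU covered by several such pairs keeps
the intersection; an HTU on a terminal branch (all covering pairs share
the one pendant OTU) keeps the union seen along that branch.  An HTU left
with no candidate order invalidates the tree; a minimal conflicting
fragment (the failing HTU plus a greedily minimised subset of its
constraining paths) is extracted and excluded from the next enumeration
round as a forbidden subtree.  `solve_phylo()` iterates enumeration and
validation until a round certifies every tree, escalating to $V + 1$ when
everything at the minimum domain is excluded — parsimony then asks for the
next-smallest domain rather than declaring failure.  Finally,
`logical_consequences()` reports what holds in *every* solution: shared
clades, fixed OTU–OTU edges, and ancestral identities (an extant gene
order that is the unique basal order of a clade in all solutions).

Two semantic choices deserve a note.  First, exclusion patterns are matched
by ordinary subgraph isomorphism (OTU labels fixed, HTUs anonymous):
a tree containing the fragment has a superset of its constraining pairs,
so the candidate-set conflict transfers and the exclusion is sound;
demanding exact HTU degrees would fail to exclude even the tree the
fragment came from.  Second, duplicate gene orders are merged before any
tree search (with a logged mapping), since two identical genomes would
occupy one node of any solution.

## The synthetic-data generator

`random_genome(n)` draws a uniform random permutation of $n$ labels with
independent fair orientations, read as circular — the natural symmetric
null model for shuffled gene orders.  `distance_distribution()` draws
independent pairs and computes exact distances.  At mitochondrial sizes
this reproduces the published behaviour of random gene orders: with 15
genes the distance mass sits at 7 (≈79%) and 6 (≈20%); with 14 genes at 6
(≈54%) and 7 (≈42%).  That concentration is the basis of the reliability
rule: an observed distance above 5 is what random, signal-free gene orders
produce, so such comparisons risk underestimating the true number of
events.

Default problem sizes were fixed once: simulations use 1000 pairs (the
binomial sampling error of a ~20% share is then ~1.3 percentage points,
comfortably inside the ±5-point comparison band used in the checks, where
500 pairs would leave less margin); property suites use genomes of 5–8
genes, where a naive breadth-first oracle can certify every distance; the
planted-ancestor experiments use 8–12 genes and 50 seeds.

What the generator does *not* emulate: real mitochondrial gene orders are
not uniform — they are correlated by shared ancestry, have conserved
blocks, unequal rearrangement-type frequencies, and occasional gene loss.
Passing the synthetic tests therefore certifies the combinatorics (exact
distances, complete enumerations, sound solver logic), not any claim about
how real lineages evolve; analyses of real data inherit the model's
assumptions (three operators, no TDRL, gains/losses annotated rather than
modelled).

## Numerical and degenerate-input choices

* Genomes need at least 2 genes to be represented and 3 for the search
  stages (blocks must be strict, so a 2-gene genome has only inversions).
* Mixed alphabets (integer-like and name-like labels) in one dataset are
  rejected; nothing meaningful can be intended.
* Canonical keys use a fixed token order (label-ascending, `+` before
  `-`), making every enumeration order deterministic and runs
  reproducible.
* A transposition that would re-insert a block at its original position is
  rejected as a no-op rather than silently accepted.
* Equal genomes are rejected by `shared_blocks()` (every proper block is
  shared; callers filter equality first).
* A linear genome's block may re-insert at either extremity; under this
  convention the worked 5-gene pair has linear distance 3 while its
  circular distance is 2, and the 3-step linear scenario provably breaks
  an endpoint-shared block, which no minimal circular scenario here does.

## Known limitations

* Exact distances are exponential in the worst case; `k_max` bounds the
  work and distances beyond it are reported as lower bounds, excluded from
  tree building.
* Tree enumeration generates all labeled trees before filtering, which is
  practical up to roughly 9–10 nodes — datasets are meant to be analysed
  as subproblems and recombined, as the solver's per-dataset contract
  states.
* Ancestral inference requires all genomes on one common gene set; with
  heterogeneous gene content, reduce the dataset to shared genes first and
  treat the removals as separate gain/loss events.
* The conjecture that *all* minimal circular paths are cut-free is only
  tested empirically here (it holds on every enumerated case); the
  machinery relies merely on the proven existence of one cut-free minimal
  path.
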