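---
title: "Gene tree correction by RF-optimal refinement and completion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene tree correction by RF-optimal refinement and completion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traction)
```

## The model

All trees here are unrooted, leaf-labeled phylogenetic trees.  Every
internal edge induces a bipartition (split) of the leaf set; the tree is
fully determined by its leaf set and its set of non-trivial splits, which
form a laminar family once each split is oriented away from a fixed
reference leaf.  The package stores trees in exactly this canonical form,
which has three consequences worth knowing:

* degree-2 nodes cannot exist, so restriction and support-collapse
  canonicalize automatically;
* isomorphism is set equality, and the Robinson–Foulds (RF) distance is
  literally the symmetric difference of two key sets;
* rooting is meaningless: parsing a rooted Newick string and re-serializing
  yields the same canonical output (children ordered by smallest descendant
  label, anchored at the lexicographically smallest leaf).

RF between trees on the same `n` leaves is normalized by `2n - 6`, the
disagreement maximum for binary trees.

## The correction procedure

Input: gene tree `t` on taxa `R`, binary reference `T` on `S ⊇ R`.

**Step 1 (refinement).**  `C_0` is the set of splits of `T|_R` compatible
with `t`.  Compatibility of one split with a tree reduces to pairwise
compatibility with each of its splits (one of the four side-intersections
empty), because pairwise compatibility over a fixed leaf set implies
setwise compatibility.  Since `C_0` additionally comes from a single tree,
`C(t) ∪ C_0` is jointly compatible and defines a unique tree `t'`
independently of insertion order — the package asserts this with
permutation tests rather than assuming it.  A binary refinement of `t`
minimizes RF to `T|_R` exactly when it contains all of `C_0`, so every
binary resolution of `t'` is co-optimal; the implementation prefers
previously collapsed edges of the uncollapsed input (restored in a
deterministic preorder of that tree, skipping any that conflict with
already-inserted reference splits — reference splits win because the
objective is RF to `T`), then finishes with seeded uniform random pairing
at each polytomy.

**Step 2 (completion).**  Removing the backbone of `T` (edges on paths
between leaves of `R`) leaves components holding the missing taxa — the
superleaves, each rooted where it met the backbone.  Because `T` is
binary, each superleaf root saw exactly two backbone edges, which restrict
to the same edge of `T|_R`: the attachment edge.  A superleaf is Type I if
that edge is shared with the gene tree (pendant attachments always are),
Type II otherwise, and the completion optimum is `RF(t*, T|_R) + 2m` with
`m` the Type II count.  The implementation attaches each superleaf as the
intact subtree it forms in `T`, in deterministic backbone-traversal
(preorder) order: Type I superleaves consider only edges whose restriction
to `R` equals their attachment edge (several such sub-edges can exist after
earlier attachments; the incremental-RF minimizer among them is taken),
Type II superleaves search every edge of the growing tree.  After the last
attachment the achieved RF is compared with the bound; any mismatch raises
an internal error instead of returning a silently suboptimal tree.  The
test suite additionally cross-checks the bound against brute-force
enumeration of all sequential attachment schedules.

When `R = S` the completion step is skipped; the skipped path is asserted
to be bit-identical to running the completion machinery with zero
superleaves.

**MUL-trees.**  For gene family trees where a species labels several
leaves, RF is not defined through bipartition multisets (two MUL-trees can
share them without being isomorphic).  The package extends the species
tree to the gene tree's copy numbers (each duplicated species becomes a
fan of copies), relabels both trees consistently over the indexed alphabet
`s_1 … s_k`, refines the differentiated gene tree against the extension,
and strips the indices.  Copies are indexed in tip-traversal order of each
tree; because permuting copy indices at an extension fan is an
automorphism, the achieved RF does not depend on the assignment — again
asserted by tests over random assignments, not assumed.  The extension is
legitimately multifurcating (a fan of `k ≥ 3` copies), so the refinement
core does not require a binary reference; binarity of the *species* tree
is still enforced at the API.  No completion is attempted in MUL mode:
copy numbers already match by construction, and missing copies are
duplication/loss events outside this problem.

## Tunable parameters

* `collapse_threshold` (default: none): edges with support strictly below
  the threshold are contracted before refinement, on the caller's scale
  (75 is the conventional bootstrap-percentage choice and the CLI
  examples' default; 50/85/90 are plausible alternatives).  Strict `<`
  means an edge with support exactly at the threshold survives; edges with
  no support annotation are never collapsed.
* `seed`: one integer determines every random choice (random resolutions,
  generator sub-seeds via the splitting rule in `derive_seed()`), so runs
  are exactly reproducible.
* `use_original_edges` (default `TRUE`): whether the uncollapsed input may
  contribute its collapsed-away edges back during resolution.

Branch lengths are parsed and re-emitted but ignored by every algorithm;
newly created edges carry no length.  Supports survive collapse but not
restriction (restriction can merge several edges into one, leaving no
well-defined value).

## The synthetic generator

`make_instance()` emulates the statistical *shape* of a gene tree
correction experiment without population-genetic simulation: species
tree → true gene tree by random NNI (local, ILS-like) and SPR
(transfer-like) moves; true gene tree → estimated gene tree by further NNI
error moves, random leaf pruning, and oracle-style supports (shared edges
draw in `[threshold, 100]`, erroneous edges in `[0, threshold)`, a flip
probability emulates misleading support).  Defaults are one discordance
NNI, one error NNI, no pruning, flip probability 0 — the smallest
departure from a clean instance in each direction; tests state their own
levels explicitly (e.g. the recovery property uses n = 20, three error
NNIs, one pruned leaf, flip 0).

What a green test does establish: exact optimality of the combinatorial
machinery on these topological instances.  What it does not: anything
about likelihood-based gene tree estimation, coalescent or transfer
processes, bootstrap behavior on sequence data, or biological correctness
of duplication placements — real data differ in exactly those ways.  In
particular, with duplications near the leaves the MUL refinement can be
RF-optimal yet imply duplications at biologically wrong locations; the
suite tests only RF-optimality, and minimizing duplication counts is a
documented non-goal.

## Numerical and degenerate-input choices

* Trees with `n ≤ 3` leaves have empty split sets and RF 0 to each other;
  all operations accept them (they arise under restriction).
  Normalized RF requires `n ≥ 4`; restriction requires `|R| ≥ 2`.
* Ties among co-optimal completions are broken by a deterministic edge
  ordering (canonical key sort), and among co-optimal resolutions by the
  seed; any co-optimal output is considered correct.
* The matching distance follows the minimum-weight perfect-matching
  construction on equal-size split sets (binary trees only), with
  orientation-minimized Hamming weights solved by an `O(k^3)`
  shortest-augmenting-path assignment solver, verified against permutation
  enumeration.  Quartet distances enumerate all `choose(n, 4)` subsets —
  intended for evaluation-scale `n`, not genomic `n`.
* The completion is the `O(n^2)`-style attachment scheme; the published
  sub-quadratic alternative is a performance upgrade, not a correctness
  change, and the test suite checks the empirical envelope instead: the
  log-log runtime slope from n = 250 to n = 1000 must stay ≤ 2.3
  (quadratic envelope plus timer-noise allowance, fixed before
  measurement).

## Known limitations

* Exactness is in the RF metric only; RF-optimal corrections can be
  biologically conservative (with no usable reference split the method
  returns a seeded random resolution).
* MUL mode solves refinement only, and its copy-index stripping assumes
  species names do not themselves end in `_<number>`.
* Newick parsing is delegated to `ape::read.tree`; the pre-scan reports
  unbalanced parentheses and missing terminators with positions, other
  malformations with ape's message.
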