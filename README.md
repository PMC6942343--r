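# traction

Non-parametric gene tree correction by RF-optimal refinement and
completion.

## The problem

Estimated gene trees are routinely incomplete (missing taxa), poorly
resolved (after collapsing low-support branches), and partly wrong (gene
tree estimation error), which degrades every downstream analysis that
consumes them — species tree estimation, duplication/loss inference,
comparative methods.  Given

* an estimated gene tree *t* on a taxon set *R* (possibly multifurcating,
  optionally with bootstrap supports on its edges), and
* a binary, singly-labeled reference species tree *T* on a superset
  *S ⊇ R*,

this package computes a binary tree *T′* on *S* such that *T′* restricted
to *R* refines *t* and the Robinson–Foulds distance RF(*T′*, *T*) is
**provably minimal** subject to that constraint.  No branch lengths,
likelihoods, or rate models are involved: the method is purely topological
and non-parametric.

## The algorithm

Two exact steps:

1. **Refinement.**  Compute `C_0`, the bipartitions of *T*|*_R* compatible
   with *t*, and add all of them; this yields the unique maximal compatible
   refinement *t′* (pairwise compatibility of splits over one leaf set
   implies setwise compatibility, so `C(t) ∪ C_0` defines one tree).  A
   binary tree refining *t* minimizes RF to *T*|*_R* **iff** it displays all
   of `C_0`; remaining polytomies are resolved first with previously
   collapsed edges of the input (when available), then uniformly at random
   (seeded), producing *t\**.
2. **Completion.**  The taxa in *S \ R* hang off the backbone of *T* (the
   edges on paths between leaves of *R*) as *superleaves*; a superleaf is
   Type I when its attachment edge restricted to *R* is shared with *t\**,
   Type II otherwise.  The minimum achievable distance is

   RF(*T′*, *T*) = RF(*t\**, *T*|*_R*) + 2·*m*,

   with *m* the number of Type II superleaves.  Each superleaf is attached
   as the intact subtree it forms in *T*, and the implementation certifies
   at run time that the bound is attained.

A multi-labeled (MUL) generalization handles gene family trees where a
species labels several leaves (gene duplication): the species tree is
extended to the gene tree's copy numbers, both trees are consistently
differentiated into singly-labeled trees over an indexed leaf set, the
refinement step is applied, and copy indices are stripped.

Also included: matching distance (minimum-weight perfect matching of split
sets) and quartet distance for evaluation; a seeded generator of synthetic
correction instances (NNI/SPR discordance, oracle-style supports, pruning);
and a command-line interface.

## Worked example

```r
library(traction)
sp <- parse_newick("(((a,b),(c,d)),e,(f,(g,x)));")        # reference, 8 taxa
g  <- parse_newick("((a,b)95,(c,e)40,d,(f,g)88);")        # gene tree, no x
res <- traction(g, sp, traction_config(collapse_threshold = 75, seed = 1))
print(res)
```

```
gene tree correction
  n_species = 8
  n_gene_leaves = 7
  rf_before = 2
  rf_star = 0
  m_type2 = 0
  lower_bound = 0
  rf_after = 0
unrooted tree: 8 leaves, 5 internal edges (binary)
(a,b,((c,d),(e,(f,(g,x)))));
```

Reading the report: the gene tree's `(c,e)` edge has support 40 < 75 and is
collapsed, leaving a tree at RF 2 from the restricted reference
(`rf_before`).  Refinement inserts the compatible reference bipartitions,
reaching RF 0 on the shared taxa (`rf_star`); the missing taxon `x` forms a
single Type I superleaf (`m_type2 = 0`), so the certified optimum
(`lower_bound`) is 0, and the returned tree attains it (`rf_after`) — the
corrected gene tree is exactly the species tree topology here.

The same run from the shell:

```sh
traction correct -g gene.nwk -s species.nwk -o corrected.nwk \
    --collapse 75 --seed 1 --report report.txt
traction compare --t1 corrected.nwk --t2 species.nwk
traction simulate --n 20 --error-nni 3 --prune 0.1 --seed 7 --outdir sim/
traction mt-correct -g family.nwk -s species.nwk -o out.nwk --seed 1
```

(`traction` is the executable installed under `inst/cli/`; equivalently
call `traction::run_cli(c("correct", ...))`.)

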