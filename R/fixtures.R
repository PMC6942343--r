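# Seeded synthetic instances.  Discordance between species tree and true
# gene tree is emulated mechanically with random NNI (local, ILS-like) and
# SPR (transfer-like) moves; estimation error with further NNI moves; and
# the bootstrap-collapse protocol with oracle-style supports (high on edges
# shared with the true tree, low on erroneous ones, optionally flipped).
# All randomness flows from one master seed through a fixed splitting rule.

#' Derive a sub-seed from a master seed
#'
#' Deterministic splitting rule so that one integer identifies a whole
#' instance; results stay within the 32-bit integer range.
#' @param master,i integers.
#' @export
derive_seed <- function(master, i) {
  as.integer((abs(as.numeric(master)) * 7919 + i * 104729) %% 2147483629) + 1L
}

#' Uniform random unrooted binary tree topology
#'
#' Built by sequential attachment: starting from the 3-leaf star, each new
#' leaf subdivides an edge chosen uniformly at random, which yields the
#' uniform distribution over labeled binary topologies.
#'
#' @param n number of leaves (at least 3).
#' @param seed integer seed.
#' @param labels optional character vector of `n` leaf labels
#'   (default `t1..tn`).
#' @return a binary `utree`.
#' @export
random_binary_tree <- function(n, seed, labels = NULL) {
  n <- as.integer(n)
  if (n < 3L) stop("n must be at least 3")
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  stopifnot(length(labels) == n)
  edges <- with_seed(seed, {
    e <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L),
                ncol = 2L, byrow = TRUE)
    nxt <- n + 1L
    for (k in seq_len(n)[-(1:3)]) {
      r <- sample.int(nrow(e), 1L)
      nxt <- nxt + 1L
      u <- e[r, 1L]; v <- e[r, 2L]
      e[r, ] <- c(u, nxt)
      e <- rbind(e, c(nxt, v), c(nxt, k))
    }
    e
  })
  edgelist_to_utree(edges, labels)
}

# integer edge list (leaves 1..n, internal nodes > n, root = n+1) -> utree
edgelist_to_utree <- function(edges, labels) {
  n <- length(labels)
  rank <- match(labels, sort(labels, method = "radix"))
  nv <- max(edges)
  kids <- vector("list", nv)
  for (r in seq_len(nrow(edges)))
    kids[[edges[r, 1L]]] <- c(kids[[edges[r, 1L]]], edges[r, 2L])
  root <- n + 1L
  order_v <- integer(0); stack <- root
  parent <- integer(nv)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_v <- c(order_v, v)
    for (w in kids[[v]]) { parent[w] <- v; stack <- c(stack, w) }
  }
  below <- vector("list", nv)
  for (i in seq_len(n)) below[[i]] <- rank[i]
  for (v in rev(order_v)) if (v != root)  # tip sets flow to parents
    below[[parent[v]]] <- c(below[[parent[v]]], below[[v]])
  internal <- setdiff(which(seq_len(nv) > n), root)
  new_utree(labels, below[internal], drop_invalid = TRUE)
}

# one random NNI move on a binary tree (RNG must be seeded by the caller):
# pick an internal edge, swap one of its two child subtrees with one of the
# two subtrees on the parent side.  Always changes exactly one bipartition.
nni_once <- function(tree) {
  k <- length(tree$clusters)
  if (!k) return(tree)
  n <- length(tree$labels)
  h <- ut_hierarchy(tree)
  e <- sample.int(k, 1L)
  ch <- c(lapply(h$kids_l[[e + 1L]], identity),
          lapply(h$kids_c[[e + 1L]], function(ci) tree$clusters[[ci]]))
  stopifnot(length(ch) == 2L)
  p <- h$parent[e]
  if (p == 0L) {
    items <- c(lapply(h$kids_l[[1L]], identity),
               lapply(h$kids_c[[1L]], function(ci) tree$clusters[[ci]]))
    others <- Filter(function(s) !setequal(s, tree$clusters[[e]]), items)
  } else {
    sib <- c(lapply(h$kids_l[[p + 1L]], identity),
             lapply(Filter(function(ci) ci != e, h$kids_c[[p + 1L]]),
                    function(ci) tree$clusters[[ci]]))
    others <- c(sib, list(setdiff(seq_len(n), tree$clusters[[p]])))
  }
  partner <- others[[sample.int(2L, 1L)]]
  new_cl <- canon_side(c(ch[[1L]], partner), n)
  clusters <- tree$clusters
  clusters[[e]] <- new_cl
  new_utree(tree$labels, clusters)
}

# one random SPR move: prune a random subtree (an edge side) and regraft it
# onto a random edge of the remainder; retries to avoid the identity move
spr_once <- function(tree) {
  n <- length(tree$labels)
  all_idx <- seq_len(n)
  sides <- c(lapply(all_idx, identity), tree$clusters,
             lapply(tree$clusters, function(cl) setdiff(all_idx, cl)))
  sides <- Filter(function(s) length(s) <= n - 2L, sides)
  for (attempt in 1:10) {
    X <- sides[[sample.int(length(sides), 1L)]]
    rest_idx <- setdiff(all_idx, X)
    rest <- restrict(tree, tree$labels[rest_idx])
    map <- match(rest$labels, tree$labels)
    rest_cl <- lapply(rest$clusters, function(s) map[s])
    X_internal <- Filter(function(s) length(s) < length(X) && all(s %in% X),
                         c(tree$clusters,
                           lapply(tree$clusters, function(cl) setdiff(all_idx, cl))))
    edges <- c(lapply(map, identity), rest_cl)
    E <- edges[[sample.int(length(edges), 1L)]]
    cand <- attach_subtree(rest_cl, sort(map), E, sort(X), X_internal)
    out <- new_utree(tree$labels, cand, drop_invalid = TRUE)
    if (!setequal(ut_keys(out), ut_keys(tree))) return(out)
  }
  out
}

#' Perturb a binary tree with random NNI and SPR moves
#'
#' Applies `nni_moves` nearest-neighbor interchanges followed by `spr_moves`
#' subtree-prune-and-regraft moves, all seeded.  The leaf set is unchanged
#' and the result is binary.  A single NNI changes exactly one bipartition
#' (RF = 2 to the input).
#'
#' @param tree a binary `utree`.
#' @param nni_moves,spr_moves non-negative move counts.
#' @param seed integer seed.
#' @return a binary `utree`.
#' @export
perturb <- function(tree, nni_moves = 0L, spr_moves = 0L, seed = 1L) {
  stopifnot(inherits(tree, "utree"), nni_moves >= 0L, spr_moves >= 0L)
  if (!is_binary(tree)) stop("perturb expects a binary tree")
  if (nni_moves == 0L && spr_moves == 0L) return(tree)
  with_seed(seed, {
    cur <- tree
    for (i in seq_len(nni_moves)) cur <- nni_once(cur)
    for (i in seq_len(spr_moves)) cur <- spr_once(cur)
    cur
  })
}

#' Emulate gene tree estimation error, support values and missing taxa
#'
#' Applies `error_nni` random NNI moves to the (true) input tree, prunes a
#' random fraction of leaves, and assigns per-edge supports oracle-style:
#' edges shared with the true tree (restricted to the retained leaves) draw
#' supports in `[threshold, 100]`, erroneous edges in `[0, threshold)`; with
#' probability `flip_prob` an edge's support category is flipped, emulating
#' misleading supports.  Collapsing the output at `threshold` with
#' `flip_prob = 0` therefore removes exactly the erroneous bipartitions.
#'
#' @param tree a binary `utree` (the true gene tree).
#' @param error_nni number of error NNI moves.
#' @param flip_prob probability of flipping an edge's support category.
#' @param prune_fraction fraction of leaves to drop (at least 3 must remain).
#' @param seed integer master seed.
#' @param threshold support scale break point (default 75, bootstrap-style).
#' @return list with `tree` (the estimated `utree`, supports attached) and
#'   `R` (character vector of retained leaves).
#' @export
degrade <- function(tree, error_nni = 0L, flip_prob = 0, prune_fraction = 0,
                    seed = 1L, threshold = 75) {
  stopifnot(inherits(tree, "utree"),
            flip_prob >= 0, flip_prob <= 1,
            prune_fraction >= 0, prune_fraction <= 1)
  n <- length(tree$labels)
  npr <- floor(prune_fraction * n)
  if (n - npr < 3L) stop("pruning would leave fewer than 3 leaves")
  est <- perturb(tree, nni_moves = error_nni, seed = derive_seed(seed, 1L))
  R <- if (npr > 0L)
    with_seed(derive_seed(seed, 2L),
              sort(sample(tree$labels, n - npr), method = "radix"))
  else tree$labels
  est_r <- restrict(est, R)
  true_r <- restrict(tree, R)
  k <- length(est_r$clusters)
  support <- with_seed(derive_seed(seed, 3L), {
    shared <- ut_keys(est_r) %in% ut_keys(true_r)
    if (flip_prob > 0) {
      flip <- stats::runif(k) < flip_prob
      shared <- xor(shared, flip)
    }
    ifelse(shared, stats::runif(k, threshold, 100),
           stats::runif(k, 0, threshold))
  })
  list(tree = new_utree(est_r$labels, est_r$clusters, support = support),
       R = R)
}

#' Generate a full synthetic correction instance
#'
#' Bundles a binary species tree, a true gene tree (species tree perturbed by
#' NNI/SPR discordance moves), and an estimated gene tree with supports and
#' missing taxa (true gene tree passed through [degrade()]).
#'
#' @param n number of species.
#' @param nni,spr discordance move counts (species tree -> true gene tree).
#' @param error_nni,flip_prob,prune_fraction,threshold estimation error
#'   parameters, see [degrade()].
#' @param seed integer master seed; sub-seeds derive via [derive_seed()].
#' @return a `correction_instance`: list with `species_tree`,
#'   `true_gene_tree`, `estimated_gene_tree`, `R`, `provenance`.
#' @export
make_instance <- function(n, nni = 1L, spr = 0L, error_nni = 1L,
                          flip_prob = 0, prune_fraction = 0,
                          threshold = 75, seed = 1L) {
  species <- random_binary_tree(n, derive_seed(seed, 11L))
  true_gene <- perturb(species, nni, spr, derive_seed(seed, 12L))
  deg <- degrade(true_gene, error_nni, flip_prob, prune_fraction,
                 derive_seed(seed, 13L), threshold)
  structure(list(species_tree = species, true_gene_tree = true_gene,
                 estimated_gene_tree = deg$tree, R = deg$R,
                 provenance = list(n = n, nni = nni, spr = spr,
                                   error_nni = error_nni,
                                   flip_prob = flip_prob,
                                   prune_fraction = prune_fraction,
                                   threshold = threshold, seed = seed)),
            class = "correction_instance")
}

#' Generate a MUL-tree duplication scenario
#'
#' `root-duplication`: the whole species tree is duplicated (every species at
#' multiplicity 2, the hard case where no extension bipartition is compatible
#' with the gene tree).  `leaf-duplication`: one random species is duplicated
#' into a cherry (multiplicity 2 for that species only).
#'
#' @param scenario `"root-duplication"` or `"leaf-duplication"`.
#' @param n number of species.
#' @param seed integer seed.
#' @return a `mul_instance`: list with `species_tree` (binary `utree`),
#'   `mul_tree` (`multree`), `scenario`.
#' @export
make_mul_instance <- function(scenario = c("root-duplication",
                                           "leaf-duplication"),
                              n, seed = 1L) {
  scenario <- match.arg(scenario)
  species <- random_binary_tree(n, derive_seed(seed, 21L))
  if (scenario == "root-duplication") {
    inner <- sub(";$", "", write_newick(species))
    mul <- parse_newick(paste0("(", inner, ",", inner, ");"), mul = TRUE)
  } else {
    s <- with_seed(derive_seed(seed, 22L), sample(species$labels, 1L))
    mult <- stats::setNames(rep(1L, n), species$labels)
    mult[s] <- 2L
    ut <- ext_indexed(species, mult)
    phy <- ut_to_phylo(ut)
    phy$tip.label <- sub("_[0-9]+$", "", phy$tip.label)
    mul <- new_multree(phy)
  }
  structure(list(species_tree = species, mul_tree = mul, scenario = scenario),
            class = "mul_instance")
}
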