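# Topological operations: restriction, RF distance, support-collapse and
# random resolution.

#' Restrict a tree to a subset of its leaves
#'
#' `T|_R`: the minimal subgraph of `T` connecting `R`, with degree-2 nodes
#' suppressed.  Its splits are exactly the non-trivial restrictions of the
#' splits of `T`.  Supports and branch lengths are not carried over (several
#' edges of `T` can merge into one edge of `T|_R`, so no single value is
#' well-defined).
#'
#' @param tree a `utree`.
#' @param subset character vector of retained leaf labels (at least 2).
#' @return a `utree` on `subset`.
#' @export
restrict <- function(tree, subset) {
  stopifnot(inherits(tree, "utree"))
  subset <- unique(as.character(subset))
  missing <- setdiff(subset, tree$labels)
  if (length(missing))
    stop("subset labels not in tree: ", paste(missing, collapse = ", "))
  if (length(subset) < 2L) stop("restriction needs at least 2 leaves")
  if (setequal(subset, tree$labels)) return(tree)
  keep_idx <- sort(match(subset, tree$labels))
  remap <- integer(length(tree$labels))
  remap[keep_idx] <- seq_along(keep_idx)
  clusters <- lapply(tree$clusters, function(cl) remap[intersect(cl, keep_idx)])
  new_utree(tree$labels[keep_idx], clusters, drop_invalid = TRUE)
}

#' Robinson-Foulds distance
#'
#' The minimum number of edge contractions and refinements transforming one
#' tree into the other; for singly-labeled trees this is the size of the
#' symmetric difference of the two bipartition sets.
#'
#' @param t1,t2 singly-labeled `utree`s on the same leaf set (restrict first
#'   if the leaf sets differ).
#' @return a non-negative integer, 0 iff the trees are isomorphic.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "utree"), inherits(t2, "utree"))
  if (!identical(t1$labels, t2$labels))
    stop("leaf sets differ; restrict the trees to a common leaf set first")
  k1 <- ut_keys(t1); k2 <- ut_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Normalized Robinson-Foulds distance
#'
#' RF divided by `2n - 6`, the maximum possible disagreement between two
#' binary trees on `n` leaves; lies in `[0, 1]`.
#'
#' @inheritParams rf_distance
#' @export
normalized_rf <- function(t1, t2) {
  n <- length(t1$labels)
  if (n < 4L) stop("normalized RF requires at least 4 leaves")
  rf_distance(t1, t2) / (2L * n - 6L)
}

#' Collapse low-support edges
#'
#' Contracts every internal edge whose support is strictly below `threshold`
#' (collapse iff `support < threshold`).  Edges without a support annotation
#' are always retained.  The comparison is on the caller's scale (0-100
#' bootstrap percentages or 0-1 proportions alike).
#'
#' @param tree a `utree` with (possibly partial) edge supports.
#' @param threshold numeric collapse threshold.
#' @return a `utree`, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold) {
  stopifnot(inherits(tree, "utree"), is.numeric(threshold))
  keep <- is.na(tree$support) | tree$support >= threshold
  new_utree(tree$labels, tree$clusters[keep], tree$support[keep],
            tree$elen[keep], tip_len = tree$tip_len)
}

# Resolve every polytomy of `tree` by uniform random sequential pairing of its
# d incident subtrees (pick a random pair, join, repeat until 3 remain); each
# join contributes one new split.  Assumes the caller has seeded the RNG.
resolve_polytomies_random <- function(tree) {
  polys <- ut_polytomies(tree)
  if (!length(polys)) return(tree)
  n <- length(tree$labels)
  new_cl <- list()
  for (p in polys) {
    items <- p$items
    while (length(items) > 3L) {
      pick <- sample.int(length(items), 2L)
      merged <- c(items[[pick[1L]]], items[[pick[2L]]])
      items <- c(items[-pick], list(merged))
      new_cl[[length(new_cl) + 1L]] <- canon_side(merged, n)
    }
  }
  new_utree(tree$labels, c(tree$clusters, new_cl),
            c(tree$support, rep(NA_real_, length(new_cl))),
            c(tree$elen, rep(NA_real_, length(new_cl))),
            tip_len = tree$tip_len)
}

#' Random binary resolution of a multifurcating tree
#'
#' Every polytomy of degree d is resolved by seeded uniform sequential pairing
#' of its d incident subtrees, so the output is a binary refinement of the
#' input, identical for identical seeds.
#'
#' @param tree a singly-labeled `utree`.
#' @param seed integer seed controlling all random choices.
#' @return a binary `utree` refining `tree`.
#' @export
random_binary_resolution <- function(tree, seed) {
  stopifnot(inherits(tree, "utree"))
  if (is_binary(tree)) return(tree)
  with_seed(seed, resolve_polytomies_random(tree))
}
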