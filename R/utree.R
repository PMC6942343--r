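# Core data model: an unrooted, singly-labeled phylogenetic tree stored in
# canonical split form.  A tree is fully determined by its leaf-label set and
# the laminar family of non-trivial splits (bipartitions), one per internal
# edge; degree-2 nodes therefore cannot be represented at all, and isomorphism
# reduces to set equality.  Each split is stored as the side that does NOT
# contain leaf index 1 (leaf indices follow the radix-sorted label order),
# which makes pairwise compatibility equivalent to "nested or disjoint".

#' Construct an unrooted tree from leaf labels and splits
#'
#' Low-level constructor used throughout the package.  Most users will obtain
#' trees from [parse_newick()] or [random_binary_tree()] instead.
#'
#' @param labels character vector of unique leaf labels (at least 2).
#' @param clusters list of integer vectors, each the set of leaf indices
#'   (relative to the radix-sorted `labels`) on one side of an internal edge.
#'   Orientation is irrelevant; sides are canonicalized internally.
#' @param support numeric vector parallel to `clusters` (edge support values,
#'   on the caller's scale; `NA` = unannotated).
#' @param elen numeric vector parallel to `clusters` (edge lengths; `NA` =
#'   absent).  Lengths are carried through I/O but ignored by every algorithm.
#' @param tip_len numeric vector parallel to the sorted labels (pendant edge
#'   lengths).
#' @param drop_invalid if `TRUE`, silently drop clusters that are trivial
#'   (fewer than 2 leaves on either side) instead of raising an error; used by
#'   operations such as restriction where triviality arises legitimately.
#' @return an object of class `utree`.
#' @export
new_utree <- function(labels, clusters = list(), support = NULL, elen = NULL,
                      tip_len = NULL, drop_invalid = FALSE) {
  if (!is.character(labels) || length(labels) < 2L)
    stop("a tree needs at least 2 character leaf labels")
  if (anyDuplicated(labels))
    stop("duplicate leaf labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         " (singly-labeled trees only; use mul = TRUE when parsing MUL-trees)")
  bad <- grepl("[(),;:]|\\s", labels) & !grepl("^'.*'$", labels)
  # reserved characters are tolerated only because write_newick() quotes them
  n <- length(labels)
  ord <- order(labels, method = "radix")
  labels <- labels[ord]
  if (is.null(tip_len)) tip_len <- rep(NA_real_, n)
  if (is.null(support)) support <- rep(NA_real_, length(clusters))
  if (is.null(elen)) elen <- rep(NA_real_, length(clusters))
  stopifnot(length(support) == length(clusters),
            length(elen) == length(clusters),
            length(tip_len) == n)

  all_idx <- seq_len(n)
  keep <- rep(TRUE, length(clusters))
  for (i in seq_along(clusters)) {
    cl <- unique(as.integer(clusters[[i]]))
    if (length(cl) && (min(cl) < 1L || max(cl) > n))
      stop("cluster leaf index out of range")
    if (1L %in% cl) cl <- setdiff(all_idx, cl)
    cl <- sort(cl)
    if (length(cl) < 2L || length(cl) > n - 2L) {
      if (drop_invalid) { keep[i] <- FALSE; next }
      stop("trivial or degenerate split (side sizes ",
           length(cl), "/", n - length(cl), ")")
    }
    clusters[[i]] <- cl
  }
  clusters <- unname(clusters[keep])
  support <- unname(support[keep]); elen <- unname(elen[keep])

  if (length(clusters)) {
    keys <- vapply(clusters, paste, "", collapse = ",")
    if (anyDuplicated(keys)) {
      first <- !duplicated(keys)
      for (i in which(first)) {
        dup <- which(keys == keys[i])
        if (length(dup) > 1L) {
          sv <- support[dup]; lv <- elen[dup]
          support[i] <- if (all(is.na(sv))) NA_real_ else sv[!is.na(sv)][1L]
          elen[i] <- if (all(is.na(lv))) NA_real_ else sum(lv, na.rm = TRUE)
        }
      }
      clusters <- clusters[first]; support <- support[first]
      elen <- elen[first]; keys <- keys[first]
    }
  } else keys <- character(0)

  ut <- structure(list(labels = labels, clusters = clusters,
                       support = support, elen = elen, tip_len = tip_len),
                  class = "utree")
  ut_hierarchy(ut)  # errors if the split set is not compatible (laminar)
  ut
}

#' @export
print.utree <- function(x, ...) {
  cat(sprintf("unrooted tree: %d leaves, %d internal edge%s%s\n",
              length(x$labels), length(x$clusters),
              if (length(x$clusters) == 1L) "" else "s",
              if (is_binary(x)) " (binary)" else ""))
  cat(write_newick(x), "\n")
  invisible(x)
}

#' Leaf labels of a tree
#' @param tree a `utree`.
#' @return character vector (sorted).
#' @export
leaf_labels <- function(tree) tree$labels

#' Number of leaves
#' @param tree a `utree`.
#' @export
n_leaves <- function(tree) length(tree$labels)

#' Is the tree fully resolved (binary)?
#'
#' A tree is fully resolved iff it admits no proper refinement, i.e. every
#' internal node has degree 3, i.e. it displays the maximal number `n - 3` of
#' non-trivial splits.
#' @param tree a `utree`.
#' @export
is_binary <- function(tree) {
  n <- length(tree$labels)
  if (n <= 3L) return(length(tree$clusters) == 0L)
  length(tree$clusters) == n - 3L
}

# Canonical string keys for the splits of a tree (one per internal edge).
ut_keys <- function(tree)
  vapply(tree$clusters, paste, "", collapse = ",")

# canonicalize an index set to the side not containing `anchor` (default 1)
canon_side <- function(idx, n, anchor = 1L) {
  idx <- sort(unique(as.integer(idx)))
  if (anchor %in% idx) idx <- setdiff(seq_len(n), idx)
  idx
}

# Build the rooted containment hierarchy of the laminar cluster family.
# The (virtual) root corresponds to the internal node adjacent to leaf 1.
# Returns parent pointers (0 = root) for clusters and leaves, plus children
# lists.  Errors if the family is not laminar, i.e. the splits are not
# jointly compatible -- this is the package's compatibility gatekeeper.
ut_hierarchy <- function(tree) {
  n <- length(tree$labels)
  k <- length(tree$clusters)
  leaf_parent <- rep(0L, n)
  parent <- integer(k)
  if (k) {
    sizes <- lengths(tree$clusters)
    ord <- order(-sizes)
    for (ci in ord) {
      cl <- tree$clusters[[ci]]
      p <- leaf_parent[cl[1L]]
      if (any(leaf_parent[cl] != p))
        stop("incompatible split set: splits do not form a laminar family")
      parent[ci] <- p
      leaf_parent[cl] <- ci
    }
  }
  kids_c <- vector("list", k + 1L)   # child clusters of node id (0-based +1)
  kids_l <- vector("list", k + 1L)   # child leaves
  for (ci in seq_len(k))
    kids_c[[parent[ci] + 1L]] <- c(kids_c[[parent[ci] + 1L]], ci)
  for (li in seq_len(n))
    kids_l[[leaf_parent[li] + 1L]] <- c(kids_l[[leaf_parent[li] + 1L]], li)
  list(parent = parent, leaf_parent = leaf_parent,
       kids_c = kids_c, kids_l = kids_l)
}

# Incident-subtree leaf sets ("items") of every polytomy of the tree.
# A node of unrooted degree d > 3 is a polytomy; items are the d leaf sets of
# the subtrees hanging off it.  Node id 0 is the hierarchy root.
ut_polytomies <- function(tree, h = ut_hierarchy(tree)) {
  n <- length(tree$labels)
  out <- list()
  ids <- c(0L, seq_along(tree$clusters))
  for (id in ids) {
    items <- c(lapply(h$kids_l[[id + 1L]], identity),
               lapply(h$kids_c[[id + 1L]], function(ci) tree$clusters[[ci]]))
    if (id != 0L)  # parent side of a cluster node
      items <- c(items, list(setdiff(seq_len(n), tree$clusters[[id]])))
    if (length(items) > 3L) out[[length(out) + 1L]] <- list(id = id, items = items)
  }
  out
}

# deterministic preorder of hierarchy nodes; children visited in order of
# their smallest descendant leaf label.  Returns, for every cluster and leaf,
# its visit rank (used for reproducible traversal orders).
ut_preorder <- function(tree, h = ut_hierarchy(tree)) {
  n <- length(tree$labels); k <- length(tree$clusters)
  leaf_rank <- integer(n); cl_rank <- integer(k)
  counter <- 0L
  visit <- function(id) {
    items <- c(h$kids_l[[id + 1L]],
               lapply(h$kids_c[[id + 1L]], function(ci) ci))
    is_leaf <- c(rep(TRUE, length(h$kids_l[[id + 1L]])),
                 rep(FALSE, length(h$kids_c[[id + 1L]])))
    mins <- vapply(seq_along(items), function(i)
      if (is_leaf[i]) items[[i]] else min(tree$clusters[[items[[i]]]]), 0L)
    for (i in order(mins)) {
      counter <<- counter + 1L
      if (is_leaf[i]) leaf_rank[items[[i]]] <<- counter
      else {
        cl_rank[items[[i]]] <<- counter
        visit(items[[i]])
      }
    }
  }
  visit(0L)
  list(leaf_rank = leaf_rank, cluster_rank = cl_rank)
}

# Are two trees isomorphic (same labels, same splits)?
ut_equal <- function(t1, t2) {
  identical(t1$labels, t2$labels) && setequal(ut_keys(t1), ut_keys(t2))
}

# does `sup` refine `sub`, i.e. C(sub) subset of C(sup)?
ut_refines <- function(sup, sub) {
  identical(sup$labels, sub$labels) && all(ut_keys(sub) %in% ut_keys(sup))
}

# run expr with a private, seeded RNG stream, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
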