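# Bipartition (split) algebra.  A bipartition A|B of a leaf set is canonically
# oriented so that the side holding the lexicographically smallest label comes
# first; equality is orientation-independent.

#' Create a bipartition A|B of a leaf set
#'
#' @param A,B disjoint, non-empty character vectors of leaf labels whose union
#'   is the full leaf set of the tree(s) the bipartition refers to.
#' @return an object of class `bipartition` with canonically ordered sides.
#' @export
bipartition <- function(A, B) {
  A <- sort(unique(as.character(A)), method = "radix")
  B <- sort(unique(as.character(B)), method = "radix")
  if (!length(A) || !length(B)) stop("both sides must be non-empty")
  if (length(intersect(A, B))) stop("sides must be disjoint")
  if (B[1L] < A[1L]) { tmp <- A; A <- B; B <- tmp }
  structure(list(A = A, B = B), class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  cat(paste(x$A, collapse = " "), "|", paste(x$B, collapse = " "), "\n")
  invisible(x)
}

#' Is a bipartition trivial?
#' @param pi a `bipartition`.
#' @return `TRUE` iff one side has a single leaf.
#' @export
is_trivial <- function(pi) min(length(pi$A), length(pi$B)) == 1L

# bipartition -> cluster indices w.r.t. a tree's sorted labels
bip_to_cluster <- function(pi, tree) {
  labs <- c(pi$A, pi$B)
  if (!setequal(labs, tree$labels))
    stop("bipartition is not over the tree's leaf set")
  canon_side(match(pi$A, tree$labels), length(tree$labels))
}

cluster_to_bip <- function(cl, tree) {
  n <- length(tree$labels)
  bipartition(tree$labels[cl], tree$labels[setdiff(seq_len(n), cl)])
}

#' Non-trivial bipartitions of a tree
#'
#' One bipartition per internal edge; trivial (pendant) bipartitions are
#' excluded, so a binary tree on n leaves yields exactly n - 3.
#'
#' @param tree a singly-labeled `utree` (MUL-trees are rejected: bipartition
#'   multisets do not determine a MUL-tree up to isomorphism).
#' @return a list of `bipartition` objects, named by a canonical key.
#' @export
bipartitions <- function(tree) {
  if (inherits(tree, "multree"))
    stop("bipartitions are not defined for MUL-trees")
  stopifnot(inherits(tree, "utree"))
  out <- lapply(tree$clusters, cluster_to_bip, tree = tree)
  names(out) <- ut_keys(tree)
  out
}

# --- compatibility ----------------------------------------------------------
# A bipartition pi is compatible with tree t iff some refinement of t displays
# it; because pairwise compatibility of splits over one leaf set implies
# setwise compatibility, this reduces to pi being pairwise compatible with
# every split of t (one of the four side intersections empty).  In canonical
# cluster form (both sides avoiding leaf 1) that is: disjoint or nested.

# which candidate clusters (list of index sets avoiding leaf 1) are pairwise
# compatible with every cluster of `tree`?  Vectorized via the intersection-
# size matrix.
clusters_compatible <- function(cands, tree) {
  k <- length(tree$clusters)
  if (!k || !length(cands)) return(rep(TRUE, length(cands)))
  n <- length(tree$labels)
  M <- matrix(0, k, n)
  for (i in seq_len(k)) M[i, tree$clusters[[i]]] <- 1
  Mc <- matrix(0, length(cands), n)
  for (j in seq_along(cands)) Mc[j, cands[[j]]] <- 1
  inter <- M %*% t(Mc)                       # k x m intersection sizes
  rs <- lengths(tree$clusters)
  cs <- lengths(cands)
  ok <- inter == 0 |                         # disjoint
    inter == matrix(cs, k, length(cands), byrow = TRUE) |  # cand nested in row
    inter == matrix(rs, k, length(cands))                  # row nested in cand
  apply(ok, 2L, all)
}

#' Is a bipartition compatible with a tree?
#'
#' @param pi a `bipartition` over the tree's leaf set (or a character vector
#'   of labels giving one side).
#' @param tree a singly-labeled `utree`.
#' @return `TRUE` iff some refinement of `tree` displays `pi`.
#' @export
is_compatible <- function(pi, tree) {
  cl <- as_cluster(pi, tree)
  clusters_compatible(list(cl), tree)[1L]
}

as_cluster <- function(pi, tree) {
  if (inherits(pi, "bipartition")) return(bip_to_cluster(pi, tree))
  if (is.character(pi)) {
    idx <- match(pi, tree$labels)
    if (anyNA(idx)) stop("labels not in tree: ",
                         paste(pi[is.na(idx)], collapse = ", "))
    return(canon_side(idx, length(tree$labels)))
  }
  stop("pi must be a bipartition or a character vector of labels")
}

#' Insert a compatible bipartition into a tree
#'
#' Returns the unique tree displaying `C(tree) \{union} {pi}`: one new edge is
#' created at the polytomy whose incident subtrees `pi` separates.  Inserting
#' a bipartition already displayed is a no-op.
#'
#' @inheritParams is_compatible
#' @return a `utree`.
#' @export
add_bipartition <- function(tree, pi) {
  cl <- as_cluster(pi, tree)
  key <- paste(cl, collapse = ",")
  if (key %in% ut_keys(tree)) return(tree)
  if (!clusters_compatible(list(cl), tree)[1L])
    stop("bipartition is incompatible with the tree")
  new_utree(tree$labels, c(tree$clusters, list(cl)),
            c(tree$support, NA_real_), c(tree$elen, NA_real_),
            tip_len = tree$tip_len)
}
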