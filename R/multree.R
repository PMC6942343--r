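# Multi-labeled (MUL) trees: gene family trees in which a species can label
# several leaves (gene duplication).  Bipartition multisets do not determine
# a MUL-tree up to isomorphism, so RF machinery is applied only after a
# consistent full differentiation that makes both trees singly-labeled over
# an indexed leaf set {s_i}.

#' MUL-tree constructor
#'
#' Wraps an `ape` "phylo" whose tip labels name species, with repeats
#' allowed.  Obtain one with `parse_newick(text, mul = TRUE)`.
#'
#' @param phy an object of class `phylo`.
#' @return an object of class `multree`.
#' @export
new_multree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  mult <- table(phy$tip.label)
  structure(list(phy = phy,
                 species = sort(names(mult)),
                 multiplicity = c(mult)),
            class = "multree")
}

#' @export
print.multree <- function(x, ...) {
  cat(sprintf("MUL-tree: %d leaves, %d species (max multiplicity %d)\n",
              length(x$phy$tip.label), length(x$species),
              max(x$multiplicity)))
  cat(ape::write.tree(x$phy), "\n")
  invisible(x)
}

# indexed label for copy i of species s
mul_index_label <- function(s, i) paste0(s, "_", i)

#' Extension of a singly-labeled tree relative to a MUL-tree
#'
#' `Ext(T, R)`: each leaf of `T` labeled by a species `s` occurring `k >= 2`
#' times in `R` is replaced by a node carrying `k` leaves labeled `s`, so the
#' extension has the same label multiplicities as `R`.
#'
#' @param T_ref a singly-labeled `utree` on the species set of `R`.
#' @param R a `multree` over the same species.
#' @return a `multree`.
#' @export
extend <- function(T_ref, R) {
  stopifnot(inherits(T_ref, "utree"), inherits(R, "multree"))
  if (!setequal(T_ref$labels, R$species))
    stop("species sets differ between the tree and the MUL-tree")
  ext <- ext_indexed(T_ref, R$multiplicity)
  phy <- ut_to_phylo(ext)
  phy$tip.label <- sub("_[0-9]+$", "", phy$tip.label)
  new_multree(phy)
}

# Ext(T, .) built directly in split space over the indexed label set:
# translate every split of T to all copies of its species, then add one
# split grouping the k copies of each duplicated species.
ext_indexed <- function(T_ref, multiplicity) {
  species <- T_ref$labels
  k_s <- multiplicity[species]
  if (anyNA(k_s)) stop("multiplicity missing for some species")
  new_labels <- unlist(lapply(species, function(s)
    vapply(seq_len(k_s[[s]]), function(i) mul_index_label(s, i), "")))
  nn <- length(new_labels)
  ord_labels <- sort(new_labels, method = "radix")
  copies_of <- lapply(species, function(s)
    match(vapply(seq_len(k_s[[s]]), function(i) mul_index_label(s, i), ""),
          ord_labels))
  names(copies_of) <- species
  clusters <- lapply(T_ref$clusters, function(cl)
    unlist(copies_of[species[cl]], use.names = FALSE))
  fans <- lapply(species[k_s >= 2L], function(s) copies_of[[s]])
  new_utree(ord_labels, c(clusters, fans), drop_invalid = TRUE)
}

#' Consistent full differentiation of two MUL-trees
#'
#' Relabels both trees over the indexed alphabet `{s_1, ..., s_k}` (copies of
#' each species indexed in tip traversal order within each tree), producing a
#' pair of singly-labeled trees on a common leaf set.
#'
#' @param r1,r2 `multree`s with identical label multiplicities.
#' @return list with `t1`, `t2` (singly-labeled `utree`s).
#' @export
differentiate <- function(r1, r2) {
  stopifnot(inherits(r1, "multree"), inherits(r2, "multree"))
  if (!setequal(r1$species, r2$species) ||
      !identical(r1$multiplicity[r1$species], r2$multiplicity[r1$species]))
    stop("the two MUL-trees must have identical label multiplicities")
  list(t1 = differentiate_one(r1), t2 = differentiate_one(r2))
}

differentiate_one <- function(r) {
  phy <- r$phy
  labs <- phy$tip.label
  new <- labs
  for (s in unique(labs)) {
    idx <- which(labs == s)
    new[idx] <- vapply(seq_along(idx), function(i) mul_index_label(s, i), "")
  }
  phy$tip.label <- new
  utree_from_phylo(phy)
}

#' Refine a MUL gene tree against a singly-labeled species tree
#'
#' The MUL-tree generalization of the refinement step: extend the species
#' tree to the gene tree's label multiplicities, differentiate both trees
#' into singly-labeled trees over a common indexed leaf set, refine with
#' every compatible bipartition of the extension, resolve the remainder at
#' random (seeded), and strip the copy indices.  The output is a binary
#' MUL-tree refining `R` with minimum RF distance to `Ext(T, R)` among all
#' binary refinements.  No completion is performed: the extension matches
#' `R`'s multiplicities by construction.
#'
#' @param R a `multree` (the gene family tree).
#' @param T_ref a binary singly-labeled `utree` on the same species set.
#' @param seed integer seed for the random resolution.
#' @return a `traction_mt_result`: list with `tree` (binary `multree`),
#'   `differentiated` (the refined indexed `utree`), `refinement`
#'   (`refinement_result` with the added-bipartition bookkeeping), and
#'   `rf_to_extension`.
#' @export
traction_mt <- function(R, T_ref, seed = 1L) {
  stopifnot(inherits(R, "multree"), inherits(T_ref, "utree"))
  if (!setequal(T_ref$labels, R$species))
    stop("species sets differ between the reference and the MUL-tree")
  if (!is_binary(T_ref)) stop("the reference tree must be binary")
  ext <- ext_indexed(T_ref, R$multiplicity)
  r_diff <- differentiate_one(R)
  if (!identical(r_diff$labels, ext$labels))
    stop("internal error: differentiation produced mismatched leaf sets")
  res <- refine_to_binary(r_diff, ext, seed = seed, binary_ref = FALSE)
  phy <- ut_to_phylo(res$t_star)
  phy$tip.label <- sub("_[0-9]+$", "", phy$tip.label)
  structure(list(tree = new_multree(phy),
                 differentiated = res$t_star,
                 refinement = res,
                 rf_to_extension = rf_distance(res$t_star, ext)),
            class = "traction_mt_result")
}

#' @export
print.traction_mt_result <- function(x, ...) {
  cat(sprintf("MUL correction: RF to extension = %d (+%d reference bipartitions)\n",
              x$rf_to_extension, length(x$refinement$added_from_reference)))
  print(x$tree)
  invisible(x)
}
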