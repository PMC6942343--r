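# RF-optimal tree refinement (step 1 of the correction pipeline).
# A binary refinement of a gene tree t minimizes the RF distance to the
# reference restricted to t's leaves, T|_R, if and only if it displays every
# bipartition of T|_R compatible with t.  Adding that whole set C_0 yields a
# unique tree t'; any binary refinement of t' is then co-optimal.

#' Reference bipartitions compatible with a gene tree
#'
#' Computes `C_0`: the bipartitions of `T|_R` (R = leaves of `t`) that are
#' compatible with `t` and not already displayed by it.  Members of `C_0` come
#' from a single tree, so `C(t)` together with `C_0` is jointly compatible.
#'
#' @param t a singly-labeled `utree` (the gene tree, possibly unresolved).
#' @param T_ref a binary singly-labeled `utree` whose leaf set contains
#'   `t`'s.
#' @return a list of `bipartition` objects (possibly empty), named by key.
#' @export
compatible_reference_bipartitions <- function(t, T_ref) {
  check_otr_inputs(t, T_ref)
  c0_core(t, T_ref)
}

# the computation itself does not need a binary reference (the refinement
# optimality argument holds for any T); the MUL pipeline refines against a
# multifurcating extension
c0_core <- function(t, T_ref) {
  TR <- restrict(T_ref, t$labels)
  cand <- TR$clusters                 # same sorted label space as t
  if (!length(cand)) return(structure(list(), names = character(0)))
  keys <- vapply(cand, paste, "", collapse = ",")
  fresh <- !(keys %in% ut_keys(t))
  ok <- clusters_compatible(cand, t) & fresh
  out <- lapply(cand[ok], cluster_to_bip, tree = t)
  names(out) <- keys[ok]
  out
}

check_otr_inputs <- function(t, T_ref) {
  stopifnot(inherits(t, "utree"), inherits(T_ref, "utree"))
  missing <- setdiff(t$labels, T_ref$labels)
  if (length(missing))
    stop("gene tree leaves absent from the reference tree: ",
         paste(missing, collapse = ", "))
  if (!is_binary(T_ref))
    stop("the reference tree must be binary (fully resolved)")
  invisible(TRUE)
}

#' Maximal compatible refinement of a gene tree
#'
#' Returns the unique tree `t'` with `C(t') = C(t) \{union} C_0`, where `C_0`
#' are the reference bipartitions compatible with `t` (see
#' [compatible_reference_bipartitions()]).  The result is independent of
#' insertion order because the union is jointly compatible.
#'
#' @inheritParams compatible_reference_bipartitions
#' @return a `utree` refining `t`.
#' @export
greedy_refine <- function(t, T_ref) {
  check_otr_inputs(t, T_ref)
  c0 <- c0_core(t, T_ref)
  if (!length(c0)) return(t)

  add <- lapply(c0, bip_to_cluster, tree = t)
  new_utree(t$labels, c(t$clusters, add),
            c(t$support, rep(NA_real_, length(add))),
            c(t$elen, rep(NA_real_, length(add))),
            tip_len = t$tip_len)
}

#' Complete a refinement to a binary tree
#'
#' Resolves any remaining polytomies of `t_prime`.  If `original` is given
#' (the uncollapsed tree whose support-collapse produced the gene tree),
#' its bipartitions that are still compatible are restored first, in
#' deterministic traversal order; reference bipartitions already in `t_prime`
#' take precedence over conflicting collapsed edges.  Any leftover polytomies
#' are resolved by seeded uniform random pairing.  All binary refinements of
#' `t_prime` attain the same (optimal) RF distance to the reference.
#'
#' @param t_prime a `utree` (typically the output of [greedy_refine()]).
#' @param original optional `utree` on the same leaf set.
#' @param seed integer seed for the random resolution.
#' @param .added_reference optional named list of reference bipartitions
#'   already inserted (bookkeeping passed through by [traction()]).
#' @return a `refinement_result`: list with elements `t_prime`, `t_star`
#'   (binary), and the disjoint bipartition-key sets `added_from_reference`,
#'   `added_from_original`, `added_random`.
#' @export
resolve <- function(t_prime, original = NULL, seed = 1L,
                    .added_reference = NULL) {
  stopifnot(inherits(t_prime, "utree"))
  cur <- t_prime
  added_orig <- character(0)
  if (!is.null(original)) {
    stopifnot(inherits(original, "utree"))
    if (!identical(original$labels, t_prime$labels))
      stop("original tree is on a different leaf set")
    if (!is_binary(cur)) {
      pre <- ut_preorder(original)
      cand_order <- order(pre$cluster_rank)
      for (ci in cand_order) {
        cl <- original$clusters[[ci]]
        key <- paste(cl, collapse = ",")
        if (key %in% ut_keys(cur)) next
        if (clusters_compatible(list(cl), cur)[1L]) {
          cur <- new_utree(cur$labels, c(cur$clusters, list(cl)),
                           c(cur$support, NA_real_), c(cur$elen, NA_real_),
                           tip_len = cur$tip_len)
          added_orig <- c(added_orig, key)
        }
      }
    }
  }
  before_rand <- ut_keys(cur)
  t_star <- if (is_binary(cur)) cur else with_seed(seed, resolve_polytomies_random(cur))
  structure(list(
    t_prime = t_prime,
    t_star = t_star,
    added_from_reference = names(.added_reference) %||% character(0),
    added_from_original = added_orig,
    added_random = setdiff(ut_keys(t_star), before_rand)
  ), class = "refinement_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf(
    "refinement: +%d reference, +%d restored, +%d random bipartitions\n",
    length(x$added_from_reference), length(x$added_from_original),
    length(x$added_random)))
  print(x$t_star)
  invisible(x)
}

# one-call convenience: greedy refinement then resolution, with bookkeeping;
# binary_ref = FALSE for the MUL path, whose reference is an extension
refine_to_binary <- function(t, T_ref, original = NULL, seed = 1L,
                             binary_ref = TRUE) {
  if (binary_ref) check_otr_inputs(t, T_ref)
  c0 <- c0_core(t, T_ref)
  if (length(c0)) {
    add <- lapply(c0, bip_to_cluster, tree = t)
    t_prime <- new_utree(t$labels, c(t$clusters, add),
                         c(t$support, rep(NA_real_, length(add))),
                         c(t$elen, rep(NA_real_, length(add))),
                         tip_len = t$tip_len)
  } else t_prime <- t
  resolve(t_prime, original = original, seed = seed, .added_reference = c0)
}
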