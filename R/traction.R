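# End-to-end correction: collapse low-support edges, refine against the
# reference, complete with the reference's missing taxa.  The output T'
# minimizes RF(T', T) subject to T'|_R refining the (collapsed) gene tree.

#' Configuration for [traction()]
#'
#' @param collapse_threshold numeric or `NULL`.  When set, internal edges of
#'   the gene tree with support strictly below this value are contracted
#'   before refinement (the input is otherwise assumed pre-collapsed).
#' @param seed integer; fully determines the output for fixed inputs.
#' @param use_original_edges when collapsing, restore collapsed edges of the
#'   original gene tree that remain compatible after refinement, before any
#'   random resolution.
#' @return a `traction_config` list.
#' @export
traction_config <- function(collapse_threshold = NULL, seed = 1L,
                            use_original_edges = TRUE) {
  if (!is.null(collapse_threshold))
    stopifnot(is.numeric(collapse_threshold), length(collapse_threshold) == 1L)
  structure(list(collapse_threshold = collapse_threshold,
                 seed = as.integer(seed),
                 use_original_edges = isTRUE(use_original_edges)),
            class = "traction_config")
}

#' Correct a gene tree against a binary reference species tree
#'
#' Step 1 refines the (optionally support-collapsed) gene tree with every
#' compatible bipartition of the reference restricted to the gene tree's
#' taxa, restores compatible collapsed edges, and resolves the remainder at
#' random (seeded).  Step 2 attaches the reference taxa missing from the gene
#' tree so that the final RF distance to the reference equals the certified
#' optimum `RF(t*, T|_R) + 2m`.  When the gene tree is complete, step 2 is a
#' no-op.
#'
#' @param gene a singly-labeled `utree` (may be multifurcating, may carry
#'   edge supports, may be missing taxa).
#' @param species a binary singly-labeled `utree` whose leaf set contains the
#'   gene tree's.
#' @param config a [traction_config()].
#' @return a `traction_result`: list with `tree` (the corrected binary
#'   `utree` on the species leaf set), `refinement` (the
#'   `refinement_result`), `completion` (`completion_result` or `NULL`), and
#'   `report` (named vector of diagnostics).
#' @examples
#' sp <- parse_newick("((a,b),c,(d,e));")
#' g  <- parse_newick("(a,b,c,d);")          # unresolved, missing e
#' traction(g, sp)$report
#' @export
traction <- function(gene, species, config = traction_config()) {
  stopifnot(inherits(gene, "utree"), inherits(species, "utree"))
  check_otr_inputs(gene, species)
  original <- NULL
  t <- gene
  if (!is.null(config$collapse_threshold)) {
    t <- collapse_low_support(gene, config$collapse_threshold)
    if (config$use_original_edges) original <- gene
  }
  res <- refine_to_binary(t, species, original = original, seed = config$seed)
  t_star <- res$t_star
  ref_R <- restrict(species, t$labels)
  rf_before <- rf_distance(t, ref_R)
  complete_input <- setequal(t$labels, species$labels)
  if (complete_input) {
    comp <- NULL
    out <- t_star
    achieved <- rf_distance(t_star, species)
    m <- 0L; bound <- achieved
  } else {
    comp <- octal_complete(t_star, species)
    out <- comp$completed
    achieved <- comp$achieved_rf; m <- comp$m; bound <- comp$lower_bound
  }
  report <- c(n_species = length(species$labels),
              n_gene_leaves = length(t$labels),
              rf_before = rf_before,
              rf_star = rf_distance(t_star, ref_R),
              m_type2 = m,
              lower_bound = bound,
              rf_after = achieved)
  structure(list(tree = out, refinement = res, completion = comp,
                 report = report),
            class = "traction_result")
}

#' @export
print.traction_result <- function(x, ...) {
  cat("gene tree correction\n")
  for (k in names(x$report)) cat(sprintf("  %s = %s\n", k, x$report[[k]]))
  print(x$tree)
  invisible(x)
}
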