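# Newick I/O.  Parsing is delegated to ape::read.tree (the field-standard
# reader); the resulting "phylo" is converted to the canonical split form, so
# any rooting or degree-2 nodes in the input are absorbed automatically.
# Numeric internal-node labels are interpreted as the support of the edge
# above that node (the RAxML bootstrap dialect).

#' Parse a Newick string into an unrooted tree
#'
#' @param text a Newick description (single tree, terminated by `;`).
#'   Branch lengths (`:x`) and numeric internal-node labels (interpreted as
#'   edge supports, e.g. bootstrap percentages) are preserved.
#' @param mul set `TRUE` to accept repeated leaf labels, returning a
#'   [multree] instead of a `utree`.
#' @return a `utree`, or a `multree` when `mul = TRUE`.
#' @examples
#' parse_newick("((a,b)90:0.1,c,(d,e)75);")
#' @export
parse_newick <- function(text, mul = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("newick parse error in: ", text)
  if (mul) return(new_multree(phy))
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         "; use mul = TRUE for MUL-trees")
  utree_from_phylo(phy)
}

# cheap well-formedness scan so that malformed input gets a useful position
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L; in_q <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_q <- !in_q
    if (in_q) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error at position ", i, ": unbalanced ')'")
    }
  }
  if (depth != 0L)
    stop("newick parse error at position ", length(chars),
         ": ", depth, " unclosed '('")
  if (!grepl(";\\s*$", text))
    stop("newick parse error at position ", nchar(text),
         ": missing terminal ';'")
  invisible(TRUE)
}

# phylo -> utree.  One split per internal (non-root) node: the tips below it.
utree_from_phylo <- function(phy) {
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("a tree needs at least 2 leaves")
  labels <- phy$tip.label
  ord <- order(labels, method = "radix")
  rank <- integer(ntip); rank[ord] <- seq_len(ntip)  # ape tip i -> sorted idx
  nnode <- phy$Nnode
  root <- ntip + 1L
  has_len <- !is.null(phy$edge.length)
  nl <- phy$node.label
  sup_of_node <- rep(NA_real_, ntip + nnode)
  if (!is.null(nl)) {
    v <- suppressWarnings(as.numeric(nl))
    sup_of_node[ntip + seq_len(nnode)] <- v
  }
  # tips below every node, bottom-up over the edge matrix
  below <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) below[[i]] <- rank[i]
  parent_edge <- integer(ntip + nnode)  # row of edge above each node
  e <- phy$edge
  for (r in seq_len(nrow(e))) parent_edge[e[r, 2L]] <- r
  # postorder: ape guarantees parents have larger numbers than... not in
  # general; do an explicit ordering by accumulating from a reordered tree
  po <- rev(order_edges_preorder(e, root))
  for (r in po) {
    p <- e[r, 1L]; ch <- e[r, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  tip_len <- rep(NA_real_, ntip)
  if (has_len)
    for (i in seq_len(ntip))
      if (parent_edge[i]) tip_len[rank[i]] <- phy$edge.length[parent_edge[i]]
  clusters <- list(); support <- numeric(0); elen <- numeric(0)
  for (v in ntip + seq_len(nnode)) {
    if (v == root) next
    clusters[[length(clusters) + 1L]] <- below[[v]]
    support <- c(support, sup_of_node[v])
    elen <- c(elen, if (has_len) phy$edge.length[parent_edge[v]] else NA_real_)
  }
  new_utree(labels, clusters, support, elen,
            tip_len = tip_len, drop_invalid = TRUE)
}

# preorder listing of edge-matrix rows from the root
order_edges_preorder <- function(e, root) {
  kids <- split(seq_len(nrow(e)), e[, 1L])
  out <- integer(nrow(e)); cnt <- 0L
  stack <- as.character(root)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    rows <- kids[[v]]
    if (is.null(rows)) next
    for (r in rows) {
      cnt <- cnt + 1L; out[cnt] <- r
      stack <- c(stack, as.character(e[r, 2L]))
    }
  }
  out[seq_len(cnt)]
}

quote_label <- function(lab) {
  ifelse(grepl("[(),;:\\[\\]]|\\s", lab), paste0("'", lab, "'"), lab)
}

fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Serialize an unrooted tree to Newick
#'
#' Output is deterministic: the tree is written from the internal node
#' adjacent to the lexicographically smallest leaf, and children are ordered
#' by their smallest descendant label, so isomorphic trees yield identical
#' strings.  Edge supports are emitted as internal-node labels and branch
#' lengths after `:` when present.
#'
#' @param tree a `utree`.
#' @return a single Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "utree"))
  n <- length(tree$labels)
  h <- ut_hierarchy(tree)
  leaf_str <- function(li) {
    s <- quote_label(tree$labels[li])
    if (!is.na(tree$tip_len[li])) s <- paste0(s, ":", fmt_num(tree$tip_len[li]))
    s
  }
  node_str <- function(id) {  # id = cluster index (>=1)
    parts <- node_children_strings(id)
    s <- paste0("(", paste(parts$str[order(parts$minlab)], collapse = ","), ")")
    if (!is.na(tree$support[id])) s <- paste0(s, fmt_num(tree$support[id]))
    if (!is.na(tree$elen[id])) s <- paste0(s, ":", fmt_num(tree$elen[id]))
    s
  }
  node_children_strings <- function(id) {
    ls <- h$kids_l[[id + 1L]]; cs <- h$kids_c[[id + 1L]]
    str <- c(vapply(ls, leaf_str, ""), vapply(cs, node_str, ""))
    minlab <- c(tree$labels[ls],
                vapply(cs, function(ci) tree$labels[min(tree$clusters[[ci]])], ""))
    list(str = str, minlab = minlab)
  }
  parts <- node_children_strings(0L)
  paste0("(", paste(parts$str[order(parts$minlab)], collapse = ","), ");")
}

# utree -> ape phylo (via the deterministic newick text)
ut_to_phylo <- function(tree) ape::read.tree(text = write_newick(tree))
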