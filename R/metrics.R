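# Evaluation distances between binary trees: matching distance (minimum-
# weight perfect matching between the two split sets, weight = orientation-
# minimized Hamming distance) and quartet distance (number of 4-taxon subsets
# whose induced quartet topologies differ), plus a one-call comparison.

#' Matching distance between two binary trees
#'
#' The two trees' split sets (each of size n - 3) are matched one-to-one so
#' as to minimize the summed Hamming distance between split indicator
#' vectors, each pair taken in its best orientation; the optimum of this
#' assignment problem is the matching distance.
#'
#' @param t1,t2 binary singly-labeled `utree`s on the same leaf set.
#' @return a non-negative integer; 0 iff the trees are isomorphic.
#' @export
matching_distance <- function(t1, t2) {
  check_metric_inputs(t1, t2)
  n <- length(t1$labels)
  k <- length(t1$clusters)
  if (k == 0L) return(0L)
  M1 <- split_matrix(t1); M2 <- split_matrix(t2)
  # Hamming distance between indicator rows; min over the two orientations
  common <- M1 %*% t(M2)
  s1 <- rowSums(M1); s2 <- rowSums(M2)
  ham <- outer(s1, s2, "+") - 2 * common
  cost <- pmin(ham, n - ham)
  as.integer(round(assignment_cost(cost)))
}

check_metric_inputs <- function(t1, t2) {
  stopifnot(inherits(t1, "utree"), inherits(t2, "utree"))
  if (!identical(t1$labels, t2$labels)) stop("leaf sets differ")
  if (!is_binary(t1) || !is_binary(t2))
    stop("matching and quartet distances are defined here for binary trees only")
  invisible(TRUE)
}

split_matrix <- function(tree) {
  n <- length(tree$labels); k <- length(tree$clusters)
  M <- matrix(0, k, n)
  for (i in seq_len(k)) M[i, tree$clusters[[i]]] <- 1
  M
}

# O(k^3) shortest-augmenting-path solution of the square assignment problem
# (Jonker-Volgenant / Hungarian with potentials).  Column index 0 is virtual.
assignment_cost <- function(a) {
  k <- nrow(a)
  stopifnot(ncol(a) == k)
  u <- numeric(k)            # row potentials
  v <- numeric(k + 1L)       # col potentials, v[1] = virtual col 0
  p <- integer(k + 1L)       # p[j+1] = row assigned to column j (0 = none)
  for (i in seq_len(k)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, k + 1L)
    way <- integer(k + 1L)
    used <- rep(FALSE, k + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(k)) {
        if (used[j + 1L]) next
        cur <- a[i0, j] - u[i0] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0L:k) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  total <- 0
  for (j in seq_len(k)) total <- total + a[p[j + 1L], j]
  total
}

# quartet topology of leaves q = c(i,j,k,l) in a binary tree with split
# membership matrix M: 1 = ij|kl, 2 = ik|jl, 3 = il|jk
quartet_topology <- function(M, q) {
  a <- M[, q[1L]]; b <- M[, q[2L]]; c <- M[, q[3L]]; d <- M[, q[4L]]
  if (any(a == b & c == d & a != c)) return(1L)
  if (any(a == c & b == d & a != b)) return(2L)
  3L
}

#' Quartet distance between two binary trees
#'
#' Counts the 4-taxon subsets whose induced unrooted quartet topologies
#' differ, by direct enumeration over all `choose(n, 4)` subsets (intended
#' for desk-scale n).
#'
#' @inheritParams matching_distance
#' @return an integer in `[0, choose(n, 4)]`.
#' @export
quartet_distance <- function(t1, t2) {
  check_metric_inputs(t1, t2)
  n <- length(t1$labels)
  if (n < 4L) stop("quartet distance requires at least 4 leaves")
  M1 <- split_matrix(t1); M2 <- split_matrix(t2)
  qs <- utils::combn(n, 4L)
  diff <- 0L
  for (j in seq_len(ncol(qs))) {
    q <- qs[, j]
    if (quartet_topology(M1, q) != quartet_topology(M2, q)) diff <- diff + 1L
  }
  diff
}

#' Compare two trees under every applicable distance
#'
#' RF and normalized RF are always computed; matching and quartet distances
#' only when both trees are binary (they are `NA` otherwise).
#'
#' @param t1,t2 singly-labeled `utree`s on the same leaf set.
#' @return a `tree_comparison`: named list `n`, `rf`, `normalized_rf`,
#'   `matching`, `quartet`.
#' @export
compare_trees <- function(t1, t2) {
  stopifnot(inherits(t1, "utree"), inherits(t2, "utree"))
  if (!identical(t1$labels, t2$labels)) stop("leaf sets differ")
  n <- length(t1$labels)
  both_binary <- is_binary(t1) && is_binary(t2)
  structure(list(
    n = n,
    rf = rf_distance(t1, t2),
    normalized_rf = if (n >= 4L) normalized_rf(t1, t2) else NA_real_,
    matching = if (both_binary) matching_distance(t1, t2) else NA_integer_,
    quartet = if (both_binary && n >= 4L) quartet_distance(t1, t2) else NA_integer_
  ), class = "tree_comparison")
}

#' @export
print.tree_comparison <- function(x, ...) {
  for (k in names(x)) cat(sprintf("%s = %s\n", k, format(x[[k]])))
  invisible(x)
}
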