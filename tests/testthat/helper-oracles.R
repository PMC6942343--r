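# Independent oracles used to verify the package's algorithms.  Everything
# here works on integer bitmasks over leaf indices 1..n (bit i-1 = leaf i)
# and explicit edge lists -- a code path deliberately disjoint from the
# package's split-key implementation.

orc_full <- function(n) bitwShiftL(1L, n) - 1L

orc_popcount <- function(m) {
  c <- 0L
  while (m > 0L) { c <- c + bitwAnd(m, 1L); m <- bitwShiftR(m, 1L) }
  c
}

# canonical mask: the side NOT containing leaf 1
orc_canon <- function(m, n) {
  if (bitwAnd(m, 1L)) bitwXor(orc_full(n), m) else m
}

# non-trivial canonical split masks of a tree given as an edge list
# (leaves 1..n, internal nodes > n, root any internal node)
orc_splits_from_edges <- function(edges, n, root = n + 1L) {
  nv <- max(edges)
  kids <- vector("list", nv)
  for (r in seq_len(nrow(edges)))
    kids[[edges[r, 1L]]] <- c(kids[[edges[r, 1L]]], edges[r, 2L])
  parent <- integer(nv)
  ordv <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ordv <- c(ordv, v)
    for (w in kids[[v]]) { parent[w] <- v; stack <- c(stack, w) }
  }
  below <- integer(nv)
  for (i in seq_len(n)) if (i <= nv) below[i] <- bitwShiftL(1L, i - 1L)
  for (v in rev(ordv)) if (v != root) below[parent[v]] <- bitwOr(below[parent[v]], below[v])
  out <- integer(0)
  for (v in ordv) if (v > n && v != root) {
    m <- orc_canon(below[v], n)
    p <- orc_popcount(m)
    if (p >= 2L && p <= n - 2L) out <- c(out, m)
  }
  sort(unique(out))
}

# all binary unrooted trees on leaves 1..n, as sorted canonical mask vectors
orc_enum_binary <- function(n) {
  stopifnot(n >= 3L)
  base <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), ncol = 2L, byrow = TRUE)
  trees <- list(base)
  k <- 3L
  while (k < n) {
    k <- k + 1L
    nxt <- list()
    for (e in trees) {
      w <- max(e) + 1L
      for (r in seq_len(nrow(e))) {
        e2 <- e
        v <- e2[r, 2L]
        e2[r, 2L] <- w
        nxt[[length(nxt) + 1L]] <- rbind(e2, c(w, v), c(w, k))
      }
    }
    trees <- nxt
  }
  lapply(trees, orc_splits_from_edges, n = n)
}

# all binary topologies on d >= 3 abstract items, as lists of item-index
# subsets (one per internal edge of the item tree); memoized
orc_item_trees_cache <- new.env(parent = emptyenv())
orc_enum_item_trees <- function(d) {
  key <- as.character(d)
  if (!is.null(orc_item_trees_cache[[key]])) return(orc_item_trees_cache[[key]])
  res <- if (d == 3L) list(list()) else {
    lapply(orc_enum_binary(d), function(masks)
      lapply(masks, function(m) which(bitwAnd(m, bitwShiftL(1L, 0:(d - 1L))) > 0L)))
  }
  orc_item_trees_cache[[key]] <- res
  res
}

# utree -> sorted canonical masks (input conversion, not oracle logic),
# optionally embedding its labels into a larger ordered label set
orc_masks_of <- function(ut, labels = ut$labels) {
  n <- length(labels)
  idx <- match(ut$labels, labels)
  stopifnot(!anyNA(idx))
  sub_mask <- sum(bitwShiftL(1L, idx - 1L))
  ms <- vapply(ut$clusters, function(cl)
    orc_canon(sum(bitwShiftL(1L, idx[cl] - 1L)), n), 0L)
  sort(unique(as.integer(ms)))
}

orc_rf <- function(m1, m2) length(setdiff(m1, m2)) + length(setdiff(m2, m1))

# masks -> utree on a given label vector (construction helper for inputs)
orc_to_utree <- function(masks, labels) {
  n <- length(labels)
  new_utree(labels, lapply(masks, function(m)
    which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0L)))
}

# --- refinement enumeration -------------------------------------------------
# all binary refinements of the tree with canonical split masks `masks` on n
# leaves, via independent polytomy detection (smallest-strict-superset
# hierarchy) and exhaustive per-polytomy resolution
orc_refinements <- function(masks, n) {
  full <- orc_full(n)
  pcs <- vapply(masks, orc_popcount, 0L)
  ord <- order(-pcs)
  parent <- integer(length(masks))   # 0 = root, else index into masks
  for (i in seq_along(masks)) {
    m <- masks[i]
    best <- 0L; bestpc <- n + 1L
    for (j in seq_along(masks)) {
      if (j == i) next
      if (bitwAnd(masks[j], m) == m && pcs[j] > pcs[i] && pcs[j] < bestpc) {
        best <- j; bestpc <- pcs[j]
      }
    }
    parent[i] <- best
  }
  # items of each node: child clusters, child leaves, (parent side)
  leaf_parent <- integer(n)
  for (li in seq_len(n)) {
    b <- bitwShiftL(1L, li - 1L)
    best <- 0L; bestpc <- n + 1L
    for (j in seq_along(masks))
      if (bitwAnd(masks[j], b) == b && pcs[j] < bestpc) { best <- j; bestpc <- pcs[j] }
    leaf_parent[li] <- best
  }
  node_items <- function(id) {
    items <- integer(0)
    for (j in seq_along(masks)) if (parent[j] == id) items <- c(items, masks[j])
    for (li in seq_len(n)) if (leaf_parent[li] == id)
      items <- c(items, bitwShiftL(1L, li - 1L))
    if (id != 0L) items <- c(items, bitwXor(full, masks[id]))
    items
  }
  per_poly <- list()
  for (id in 0:length(masks)) {
    items <- node_items(id)
    if (length(items) > 3L) {
      d <- length(items)
      alt <- lapply(orc_enum_item_trees(d), function(itree)
        vapply(itree, function(subset)
          orc_canon(as.integer(sum(items[subset])), n), 0L))
      per_poly[[length(per_poly) + 1L]] <- alt
    }
  }
  if (!length(per_poly)) return(list(sort(masks)))
  combos <- list(integer(0))
  for (alt in per_poly) {
    combos <- unlist(lapply(combos, function(base)
      lapply(alt, function(add) c(base, add))), recursive = FALSE)
  }
  lapply(combos, function(add) sort(unique(c(masks, add))))
}

# --- BFS edit-distance oracle for RF ---------------------------------------
# minimum number of single-split contractions/additions turning tree 1 into
# tree 2; explicit breadth-first search over split-set states
orc_bfs_rf <- function(m1, m2, n) {
  all_masks <- Filter(function(m) {
    p <- orc_popcount(m)
    p >= 2L && p <= n - 2L && !bitwAnd(m, 1L)
  }, seq_len(orc_full(n)))
  compat <- function(a, b) {
    i <- bitwAnd(a, b)
    i == 0L || i == a || i == b
  }
  keyof <- function(ms) paste0("k", paste(ms, collapse = ","))
  target <- keyof(sort(m2))
  start <- sort(m1)
  if (keyof(start) == target) return(0L)
  seen <- new.env(parent = emptyenv())
  assign(keyof(start), TRUE, envir = seen)
  frontier <- list(start)
  depth <- 0L
  repeat {
    depth <- depth + 1L
    nxt <- list()
    for (st in frontier) {
      neigh <- list()
      for (i in seq_along(st)) neigh[[length(neigh) + 1L]] <- st[-i]
      for (m in all_masks) {
        if (m %in% st) next
        if (all(vapply(st, function(s) compat(m, s), TRUE)))
          neigh[[length(neigh) + 1L]] <- sort(c(st, m))
      }
      for (ns in neigh) {
        k <- keyof(ns)
        if (k == target) return(depth)
        if (!exists(k, envir = seen)) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- ns
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) stop("BFS exhausted without reaching target")
  }
}

# --- completion oracle ------------------------------------------------------
# superleaf components of T (splits `Tmasks` on n leaves, retained mask R):
# maximal R-free edge sides, with their internal splits
orc_superleaves <- function(Tmasks, n, Rmask) {
  full <- orc_full(n)
  sides <- unique(c(vapply(seq_len(n), function(i) bitwShiftL(1L, i - 1L), 0L),
                    Tmasks, vapply(Tmasks, function(m) bitwXor(full, m), 0L)))
  rfree <- Filter(function(s) bitwAnd(s, Rmask) == 0L, sides)
  maximal <- Filter(function(s)
    !any(vapply(rfree, function(o) o != s && bitwAnd(o, s) == s, TRUE)), rfree)
  lapply(maximal, function(X) {
    internal <- Filter(function(s)
      s != X && bitwAnd(X, s) == s, sides)
    list(X = X, internal = internal)
  })
}

# restriction of canonical masks to the leaves in `pmask`; re-canonicalized
# w.r.t. the lowest set bit of pmask
orc_restrict_masks <- function(masks, n, pmask) {
  low <- bitwAnd(pmask, -pmask)
  out <- integer(0)
  for (m in masks) {
    a <- bitwAnd(m, pmask)
    b <- bitwAnd(bitwXor(orc_full(n), m), pmask)
    if (orc_popcount(a) < 2L || orc_popcount(b) < 2L) next
    out <- c(out, if (bitwAnd(a, low)) b else a)
  }
  sort(unique(out))
}

# attach subtree X (with internal split sides `internal`) onto the edge with
# side E of the tree given by raw sides `cl` over placed leaves `pmask`
orc_attach <- function(cl, pmask, E, X, internal) {
  rest <- bitwXor(pmask, E)
  ext <- vapply(cl, function(s) {
    if (bitwAnd(s, E) == E || bitwAnd(s, rest) == rest) bitwOr(s, X) else s
  }, 0L)
  out <- c(ext, internal, E, bitwOr(E, X), X)
  p2 <- bitwOr(pmask, X)
  np <- orc_popcount(p2)
  low <- bitwAnd(p2, -p2)
  out <- Filter(function(s) {
    a <- orc_popcount(s)
    a >= 2L && a <= np - 2L
  }, out)
  canon <- vapply(out, function(s) if (bitwAnd(s, low)) bitwXor(p2, s) else s, 0L)
  sort(unique(as.integer(canon)))
}

# exhaustive minimum completion RF: all superleaf orders x all edge choices
orc_complete_min <- function(tmasks, Rmask, Tmasks, n) {
  sls <- orc_superleaves(Tmasks, n, Rmask)
  rec <- function(cl, pmask, remaining) {
    if (!length(remaining)) {
      ref <- orc_restrict_masks(Tmasks, n, pmask)
      low <- bitwAnd(pmask, -pmask)
      canon <- vapply(cl, function(s)
        if (bitwAnd(s, low)) bitwXor(pmask, s) else s, 0L)
      return(orc_rf(sort(unique(as.integer(canon))), ref))
    }
    best <- Inf
    for (si in seq_along(remaining)) {
      sl <- remaining[[si]]
      bits <- Filter(function(b) bitwAnd(pmask, b) > 0L,
                     bitwShiftL(1L, 0:(n - 1L)))
      edges <- c(as.list(bits), as.list(cl))
      for (E in edges) {
        nc <- orc_attach(cl, pmask, E, sl$X, sl$internal)
        v <- rec(nc, bitwOr(pmask, sl$X), remaining[-si])
        if (v < best) best <- v
      }
    }
    best
  }
  rec(as.list(tmasks), Rmask, sls)
}

# --- metric oracles ---------------------------------------------------------
orc_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in orc_perms(k - 1L))
    for (pos in 0:(k - 1L))
      out[[length(out) + 1L]] <- append(p, k, after = pos)
  out
}

orc_matching <- function(t1, t2) {
  n <- length(t1$labels)
  v1 <- lapply(t1$clusters, function(cl) { z <- rep(0L, n); z[cl] <- 1L; z })
  v2 <- lapply(t2$clusters, function(cl) { z <- rep(0L, n); z[cl] <- 1L; z })
  k <- length(v1)
  if (!k) return(0L)
  w <- function(a, b) { h <- sum(a != b); min(h, n - h) }
  best <- Inf
  for (p in orc_perms(k)) {
    tot <- sum(vapply(seq_len(k), function(i) w(v1[[i]], v2[[p[i]]]), 0))
    if (tot < best) best <- tot
  }
  as.integer(best)
}

# quartet distance by restricting both mask sets to each 4-subset
orc_quartet <- function(m1, m2, n) {
  qtop <- function(masks, q) {
    qm <- sum(bitwShiftL(1L, q - 1L))
    for (m in masks) {
      a <- bitwAnd(m, qm)
      if (orc_popcount(a) == 2L) return(min(a, bitwXor(qm, a)))
      b <- bitwAnd(bitwXor(orc_full(n), m), qm)
      if (orc_popcount(b) == 2L) return(min(b, bitwXor(qm, b)))
    }
    0L  # unresolved (cannot happen for binary inputs)
  }
  qs <- utils::combn(n, 4L)
  d <- 0L
  for (j in seq_len(ncol(qs)))
    if (qtop(m1, qs[, j]) != qtop(m2, qs[, j])) d <- d + 1L
  d
}
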