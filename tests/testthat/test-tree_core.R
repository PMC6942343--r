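# tree substrate: newick I/O, bipartition algebra, restriction, RF

test_that("newick parsing follows the support-label dialect", {
  t1 <- ut("((a,b)90:0.1,c,(d,e)75);")
  bp <- bipartitions(t1)
  expect_setequal(names(bp), c("3,4,5", "4,5"))  # cde | de sides (a = leaf 1)
  sup <- setNames(t1$support, ut_keys_test(t1))
  expect_equal(unname(sup["3,4,5"]), 90)  # the ab|cde edge
  expect_equal(unname(sup["4,5"]), 75)    # the de|abc edge

  t2 <- ut("(a,b);")
  expect_equal(n_leaves(t2), 2L)
  expect_length(t2$clusters, 0L)
  expect_equal(write_newick(t2), "(a,b);")

  expect_error(parse_newick("((a,b),c;"), "position")
  expect_error(parse_newick("((a,b),(a,c));"), "duplicate")
  expect_s3_class(parse_newick("((a,b),(a,c));", mul = TRUE), "multree")
})

test_that("write/parse round-trips are isomorphic and idempotent", {
  expect_match(write_newick(ut("((a,b)90,c,(d,e));")), "\\)90")
  for (i in 1:100) {
    n <- 4L + (i %% 17L)
    tr <- random_contracted(n, seed = 1000L + i, p_keep = 0.7)
    txt <- write_newick(tr)
    re <- parse_newick(txt)
    expect_identical(leaf_labels(re), leaf_labels(tr))
    expect_setequal(ut_keys_test(re), ut_keys_test(tr))
    expect_identical(write_newick(re), txt)  # idempotent serialization
  }
})

test_that("serialization is anchor/rooting invariant", {
  # same unrooted tree written from different rooted newick representations
  forms <- c("((a,b),(c,(d,e)));", "(((d,e),c),(b,a));", "(c,(d,e),(a,b));",
             "((e,d),(c,(a,b)));")
  out <- vapply(forms, function(s) write_newick(parse_newick(s)), "")
  expect_length(unique(out), 1L)
})

test_that("bipartitions enumerates exactly the internal edges", {
  expect_setequal(names(bipartitions(ut("((a,b),c,(d,e));"))),
                  c("3,4,5", "4,5"))
  expect_length(bipartitions(ut("(a,b,c,d,e);")), 0L)
  for (n in c(5L, 9L, 14L)) {
    bt <- random_binary_tree(n, seed = n)
    expect_length(bipartitions(bt), n - 3L)
  }
  expect_error(bipartitions(parse_newick("((a,a),b,c);", mul = TRUE)),
               "MUL")
})

test_that("restriction matches split-wise restriction", {
  tr <- restrict(ut("((a,b),x,(c,d));"), c("a", "b", "c", "d"))
  expect_setequal(ut_keys_test(tr), "3,4")    # ab|cd survives, x suppressed
  full <- ut("((a,b),c,(d,e));")
  expect_identical(restrict(full, leaf_labels(full)), full)
  expect_length(restrict(full, c("a", "c", "e"))$clusters, 0L)
  expect_error(restrict(full, c("a", "z")), "z")
  expect_error(restrict(full, "a"), "at least 2")
  # property: C(T|_R) = non-trivial restrictions of C(T), vs the mask oracle
  for (i in 1:25) {
    n <- 6L + (i %% 5L)
    T0 <- random_binary_tree(n, seed = 300L + i)
    m <- 4L + (i %% (n - 4L))
    R <- seeded(i, sort(sample(T0$labels, m)))
    got <- restrict(T0, R)
    pmask <- sum(bitwShiftL(1L, match(R, T0$labels) - 1L))
    exp_masks <- orc_restrict_masks(orc_masks_of(T0), n, pmask)
    expect_setequal(orc_masks_of(got, labels = sort(R)),
                    # re-index oracle masks into the restricted label space
                    vapply(exp_masks, function(mm) {
                      idx <- which(bitwAnd(mm, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
                      sub <- match(T0$labels[idx], sort(R))
                      orc_canon(sum(bitwShiftL(1L, sub - 1L)), length(R))
                    }, 0L))
  }
})

test_that("compatibility follows the four-intersection rule", {
  expect_true(is_compatible(bipartition(c("d", "e"), c("a", "b", "c")),
                            ut("(a,b,(c,d,e));")))
  expect_false(is_compatible(bipartition(c("a", "b"), c("c", "d", "e")),
                             ut("((a,c),b,d,e);")))
  t0 <- random_binary_tree(8, seed = 11)
  for (pi in bipartitions(t0)) expect_true(is_compatible(pi, t0))
  expect_error(is_compatible(bipartition("a", "b"), t0), "leaf set")
})

test_that("add_bipartition inserts exactly one edge, order-independently", {
  t1 <- add_bipartition(ut("(a,b,(c,d,e));"), c("d", "e"))
  expect_setequal(ut_keys_test(t1), c("3,4,5", "4,5"))
  expect_identical(add_bipartition(t1, c("d", "e")), t1)  # no-op re-insert
  expect_error(add_bipartition(ut("((a,c),b,d,e);"), c("a", "b")),
               "incompatible")
  # inserting all splits of a binary tree into the star reconstructs it
  for (i in 1:20) {
    B <- random_binary_tree(7, seed = 500L + i)
    star <- new_utree(B$labels, list())
    perm <- seeded(i, sample(seq_along(B$clusters)))
    cur <- star
    for (ci in perm)
      cur <- add_bipartition(cur, B$labels[B$clusters[[ci]]])
    expect_setequal(ut_keys_test(cur), ut_keys_test(B))
  }
})

test_that("RF distance is the bipartition symmetric difference and a metric", {
  a <- ut("((a,b),c,(d,e));"); b <- ut("((a,c),b,(d,e));")
  expect_equal(rf_distance(a, a), 0L)
  expect_equal(rf_distance(a, b), 2L)
  expect_equal(normalized_rf(a, b), 0.5)
  star <- new_utree(a$labels, list())
  expect_equal(rf_distance(a, star), 2L)  # n - 3
  expect_error(rf_distance(a, ut("((a,b),c,(d,f));")), "leaf set")
  expect_error(normalized_rf(ut("(a,b,c);"), ut("(a,b,c);")), "4")
  # identity, symmetry, triangle on random triples
  for (i in 1:30) {
    n <- 5L + (i %% 4L)
    x <- random_contracted(n, 700L + i); y <- random_contracted(n, 800L + i)
    z <- random_contracted(n, 900L + i)
    expect_equal(rf_distance(x, y), rf_distance(y, x))
    expect_equal(rf_distance(x, x), 0L)
    expect_lte(rf_distance(x, z), rf_distance(x, y) + rf_distance(y, z))
  }
})

test_that("maximally different binary trees attain normalized RF 1", {
  t1 <- ut("((a,b),(c,d),e);"); t2 <- ut("((a,c),(b,d),e);")
  expect_equal(rf_distance(t1, t2), 4L)
  expect_equal(normalized_rf(t1, t2), 1)
})

test_that("collapse_low_support contracts strictly-below-threshold edges", {
  t1 <- ut("((a,b)90,(c,d)60,e);")
  c75 <- collapse_low_support(t1, 75)
  expect_setequal(ut_keys_test(c75), "3,4,5")   # only ab|cde survives
  expect_identical(ut_keys_test(collapse_low_support(t1, 0)),
                   ut_keys_test(t1))
  expect_length(collapse_low_support(t1, 101)$clusters, 0L)
  # threshold equal to the support keeps the edge (strict <)
  expect_length(collapse_low_support(t1, 60)$clusters, 2L)
  # unannotated edges are never collapsed
  t2 <- ut("((a,b)50,(c,d),e);")
  expect_setequal(ut_keys_test(collapse_low_support(t2, 75)), "3,4")
})

test_that("random resolution refines, is seeded, and is uniform at degree 4", {
  bt <- random_binary_tree(9, seed = 2)
  expect_identical(random_binary_resolution(bt, 5), bt)
  for (i in 1:500) {
    tr <- random_contracted(5L + (i %% 6L), seed = 2000L + i, p_keep = 0.4)
    res <- random_binary_resolution(tr, seed = i)
    expect_true(is_binary(res))
    expect_true(all(ut_keys_test(tr) %in% ut_keys_test(res)))
  }
  tr <- random_contracted(8, seed = 123, p_keep = 0.4)
  expect_identical(write_newick(random_binary_resolution(tr, 42)),
                   write_newick(random_binary_resolution(tr, 42)))
  # degree-4 polytomy: the three resolutions each at frequency 1/3 +- 0.02
  quad <- ut("(a,b,c,d);")
  counts <- table(vapply(1:10000, function(s)
    ut_keys_test(random_binary_resolution(quad, s)), ""))
  expect_length(counts, 3L)
  expect_true(all(abs(counts / 10000 - 1 / 3) <= 0.02))
})
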