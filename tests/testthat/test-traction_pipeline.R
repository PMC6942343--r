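# end-to-end correction and command-line interface

test_that("unconstrained refinement returns the species tree itself", {
  sp <- ut("((a,b),c,(d,e));")
  star <- new_utree(letters[1:5], list())
  out <- traction(star, sp)
  expect_setequal(ut_keys_test(out$tree), ut_keys_test(sp))
  expect_equal(unname(out$report["rf_after"]), 0L)
})

test_that("incomplete gene trees are completed at the certified optimum", {
  g <- ut("((a,c),b,d);")
  sp <- ut("((a,b),x,(c,d));")
  out <- traction(g, sp)
  expect_equal(unname(out$report["rf_after"]), 4L)
  expect_identical(leaf_labels(out$tree), leaf_labels(sp))
  expect_true(is_binary(out$tree))
})

test_that("output restricted to R always refines the collapsed gene tree", {
  for (i in 1:40) {
    inst <- make_instance(n = 10L, nni = 2L, spr = 1L, error_nni = 2L,
                          prune_fraction = 0.15, seed = 7000L + i)
    cfg <- traction_config(collapse_threshold = 75, seed = i)
    out <- traction(inst$estimated_gene_tree, inst$species_tree, cfg)
    collapsed <- collapse_low_support(inst$estimated_gene_tree, 75)
    back <- restrict(out$tree, inst$R)
    expect_true(all(ut_keys_test(collapsed) %in% ut_keys_test(back)))
    expect_equal(unname(out$report["rf_after"]),
                 unname(out$report["lower_bound"]))
  }
})

test_that("collapse + recoverable edges give perfect recovery", {
  # species with 2 contracted edges and 1 pruned leaf recovers RF 0 when all
  # contracted bipartitions are compatible and the superleaf is Type I
  for (i in 1:25) {
    sp <- random_binary_tree(10, seed = 7500L + i)
    drop <- seeded(i, sample(seq_along(sp$clusters), 2L))
    g0 <- new_utree(sp$labels, sp$clusters[-drop])
    R <- setdiff(sp$labels, seeded(1000L + i, sample(sp$labels, 1L)))
    g <- restrict(g0, R)
    out <- traction(g, sp, traction_config(seed = i))
    expect_equal(unname(out$report["rf_after"]), 0L)
    expect_setequal(ut_keys_test(out$tree), ut_keys_test(sp))
  }
})

test_that("the complete-gene fast path equals the explicit completion path", {
  for (i in 1:15) {
    sp <- random_binary_tree(9, seed = 7700L + i)
    g <- random_contracted(9, seed = 7800L + i, p_keep = 0.5)
    out <- traction(g, sp, traction_config(seed = i))
    t_star <- out$refinement$t_star
    via_octal <- octal_complete(t_star, sp)
    expect_identical(write_newick(out$tree), write_newick(via_octal$completed))
    expect_equal(unname(out$report["rf_after"]), via_octal$achieved_rf)
  }
})

test_that("the seed fully determines the output", {
  inst <- make_instance(n = 12L, nni = 2L, error_nni = 3L,
                        prune_fraction = 0.1, seed = 99L)
  cfg <- traction_config(collapse_threshold = 75, seed = 7L)
  o1 <- traction(inst$estimated_gene_tree, inst$species_tree, cfg)
  o2 <- traction(inst$estimated_gene_tree, inst$species_tree, cfg)
  expect_identical(write_newick(o1$tree), write_newick(o2$tree))
})

test_that("precondition violations raise informative errors", {
  expect_error(traction(ut("(a,b,c,d,e);"), ut("(a,b,c,d,e);")), "binary")
  expect_error(traction(ut("(a,b,z,d);"), ut("((a,b),c,(d,e));")), "z")
})

test_that("the CLI corrects, reports, and is byte-deterministic", {
  d <- withr::local_tempdir()
  st <- run_cli(c("simulate", "--n", "10", "--error-nni", "2",
                  "--prune", "0.1", "--seed", "5", "--outdir",
                  file.path(d, "sim")))
  expect_equal(st, 0L)
  expect_setequal(list.files(file.path(d, "sim")),
                  c("species.nwk", "true_gene.nwk", "est_gene.nwk",
                    "manifest.txt"))
  g <- file.path(d, "sim", "est_gene.nwk")
  s <- file.path(d, "sim", "species.nwk")
  o1 <- file.path(d, "o1.nwk"); o2 <- file.path(d, "o2.nwk")
  rep1 <- file.path(d, "r1.txt")
  st1 <- run_cli(c("correct", "-g", g, "-s", s, "-o", o1,
                   "--collapse", "75", "--seed", "1", "--report", rep1))
  st2 <- run_cli(c("correct", "-g", g, "-s", s, "-o", o2,
                   "--collapse", "75", "--seed", "1"))
  expect_equal(st1, 0L)
  expect_identical(readLines(o1), readLines(o2))   # determinism
  out <- parse_newick(readLines(o1))
  sp <- parse_newick(readLines(s))
  expect_true(is_binary(out))
  expect_identical(leaf_labels(out), leaf_labels(sp))
  expect_true(any(grepl("^rf_after=", readLines(rep1))))
})

test_that("the CLI fails cleanly on bad input", {
  d <- withr::local_tempdir()
  writeLines("(a,b,c,d,e);", file.path(d, "star.nwk"))
  writeLines("((a,b),c,(d,e));", file.path(d, "bin.nwk"))
  msgs <- capture.output(
    st <- run_cli(c("correct", "-g", file.path(d, "bin.nwk"),
                    "-s", file.path(d, "star.nwk"),
                    "-o", file.path(d, "x.nwk"))),
    type = "message")
  expect_equal(st, 1L)
  expect_true(any(grepl("binary", msgs)))
  expect_equal(run_cli(c("correct", "-g", "missing.nwk")), 1L)
  expect_equal(run_cli(c("frobnicate")), 1L)
  expect_equal(run_cli(character(0)), 1L)
})

test_that("the CLI compares trees with selectable metrics", {
  d <- withr::local_tempdir()
  writeLines("((a,b),c,(d,e));", file.path(d, "1.nwk"))
  writeLines("((a,c),b,(d,e));", file.path(d, "2.nwk"))
  out <- capture.output(st <- run_cli(c("compare",
                                        "--t1", file.path(d, "1.nwk"),
                                        "--t2", file.path(d, "2.nwk"))))
  expect_equal(st, 0L)
  expect_true(all(c("rf=2", "normalized_rf=0.5", "matching=2", "quartet=2")
                  %in% out))
  out2 <- capture.output(st2 <- run_cli(c("compare",
                                          "--t1", file.path(d, "1.nwk"),
                                          "--t2", file.path(d, "2.nwk"),
                                          "--metrics", "rf")))
  expect_true("rf=2" %in% out2 && !any(grepl("quartet", out2)))
})
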