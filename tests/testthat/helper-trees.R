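# shared conveniences for building test instances with the package's own
# generators (inputs only; expected values come from the oracles)

ut <- function(text) parse_newick(text)

ut_keys_test <- function(tree)
  vapply(tree$clusters, paste, "", collapse = ",")
keyset_of <- function(tree) sort(ut_keys_test(tree))

seeded <- function(seed, expr) traction:::with_seed(seed, expr)

# random tree with a random subset of its internal edges contracted
random_contracted <- function(n, seed, p_keep = 0.5, labels = NULL) {
  bt <- random_binary_tree(n, seed, labels = labels)
  k <- length(bt$clusters)
  keep <- seeded(derive_seed(seed, 99L), stats::runif(k) < p_keep)
  new_utree(bt$labels, bt$clusters[keep])
}
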