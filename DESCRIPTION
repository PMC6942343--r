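Package: traction
Title: Non-Parametric Gene Tree Correction by RF-Optimal Refinement and Completion
Version: 1.0.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Corrects an estimated gene tree against a binary reference species
    tree by (i) collapsing low-support branches, (ii) refining the resulting
    polytomies with every compatible bipartition of the reference tree, and
    (iii) completing the tree with the reference tree's missing taxa, so that
    the Robinson-Foulds distance to the reference is provably minimal subject
    to the output refining the input gene tree. Includes the multi-labeled
    (MUL) tree generalization for gene families with duplications, the
    matching and quartet evaluation distances, a seeded synthetic-instance
    generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
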