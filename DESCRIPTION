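Package: cirperm
Title: Structure Modeling and Termini Linker Design for Circularly
    Permuted Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative structure modeling for circularly permuted
    proteins (CPMs). Builds pseudo-circularly-permuted templates by
    residue-record rotation, designs peptide linkers that bridge the
    native termini using a bootstrap vote ensemble (decision trees plus
    small neural networks) over inverse-square-distance structural
    features, estimates linker length from the termini distance, screens
    candidate sequences with an energy backend, and refines models by an
    exhaustive rigid-body search hinged at the circular-permutation site.
    Ships a deterministic synthetic-fixture generator (ideal chains, CP
    pairs with planted linkers, separable training sets) and a scaled
    independent-test harness, so the whole protocol runs without external
    modeling software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    nnet,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
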