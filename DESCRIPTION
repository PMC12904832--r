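Package: BitRepro
Title: Bit-Reproducible Parallel Reduction with Fixed Operation Order
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compile-ahead, bit-reproducible distributed reduction and
    all-reduction for arbitrary associative operators. The operation order is
    fixed by a binary reduction tree over the globally ordered input elements
    and is therefore independent of the number of processing elements (PEs)
    and of how elements are distributed across them. Communication is routed
    along a k-nomial tree with the minimal p-1 messages; each intermediate
    reduction is assigned to the lowest common ancestor PE of its operands'
    owners, and per-PE stack-machine schedules are compiled in a
    pre-processing step. Includes a deterministic simulated execution engine,
    sequential oracles and non-reproducible baselines, an exact summation
    reference, a Jukes-Cantor pruning-algorithm likelihood demonstrator that
    accumulates per-site log-likelihoods in fixed alignment order, relative
    Robinson-Foulds tree divergence metrics, and deterministic generators for
    all test inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ape,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
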