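Package: phylograd
Title: Linear-Time Branch-Length Gradients for Phylogenetic Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes phylogenetic data log-likelihoods and, in linear time
    in the number of taxa, the gradient of the log-likelihood with respect
    to all branch-length-specific parameters.  Implements Felsenstein's
    post-order pruning recursion with underflow-safe rescaling, the
    pre-order partial-likelihood recursion, and the any-node likelihood
    identity that yields the full branch-length gradient as weighted inner
    products of post- and pre-order partials.  Supports general
    time-reversible nucleotide models, Goldman-Yang-style codon models,
    Markov-modulated compositions, and discrete-gamma rate heterogeneity,
    together with site-pattern compression, an exact continuous-time
    Markov chain simulator, slow independent oracle computations for
    validation, a minimal Hamiltonian Monte Carlo sampler over branch
    lengths, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
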