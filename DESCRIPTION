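Package: codonsites
Title: Transition-Bias and Pretermination-Aware Synonymous Site Counting and dN/dS
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Counts synonymous (S) and non-synonymous (NS) sites per codon
    under the classic equal-rate model and under a modified model that
    weights transitions by the transition:transversion rate ratio kappa and
    removes nonsense substitutions in pretermination codons. Provides
    pairwise gene dN/dS under both site models (single-substitution codon
    differences only), the observed/expected synonymous polymorphism
    statistic fS over multi-strain codon alignments with degeneracy-class
    comparisons, and a kappa-parameterised codon substitution simulator used
    to validate the neutral-limit behaviour of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
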