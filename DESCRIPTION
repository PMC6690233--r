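Package: quartetstar
Title: Star and Resolved Quartet Phylogenies Under JC69 with Continuous
    Gamma Rates
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact maximum-likelihood evaluation of four-taxon (quartet)
    trees under the Jukes-Cantor (JC69) substitution model, with either a
    constant rate across sites or continuous gamma-distributed rate
    heterogeneity marginalised by quadrature (not discretised into rate
    categories).  Site patterns are collapsed into the 15 JC69
    equivalence classes so that whole alignments are represented by
    compact pattern counts.  Provides bounded maximum-likelihood fitting
    of star and resolved quartet topologies, likelihood-ratio tests of
    the star tree against the best resolved tree, a site-pattern
    goodness-of-fit test with parametric bootstrap, and a seeded
    sequence-evolution simulator.  Together these expose the "starless
    bias": a likelihood method rejecting the star tree for sequences that
    are exactly equidistant from one another, and the accompanying
    topology-dependence of the estimated gamma shape parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    pracma,
    stats
Suggests:
    jsonlite,
    Matrix,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
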