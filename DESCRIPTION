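Package: lexnetgrow
Title: Simulated Growth and Graph-Theoretic Analysis of Orthographic
    Lexicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the staged, frequency-sensitive growth of
    orthographic lexicons for virtual language learners and analyses the
    resulting Levenshtein-distance-1 neighbourhood networks with graph
    theory.  Provides a synthetic frequency-lexicon generator with
    Zipfian token frequencies and a tunable frequency-length coupling, a
    probability-proportional-to-size sampler without replacement, an
    indexed edit-distance-1 neighbour graph builder that scales beyond
    one hundred thousand word types, small-world network measures (mean
    degree, degree distribution, average path length, diameter,
    clustering coefficient, lexical-hermit accounting), developmental
    trend statistics (one-way ANOVA, Tukey HSD, orthogonal polynomial
    trends, log-log power-law fits, correlation power), and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
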