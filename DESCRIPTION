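Package: microkey
Title: Key-Player Analysis of Microbial Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers co-occurrence networks from OTU count tables with the
    sparCC compositional correlation procedure, computes global network
    topology and node centralities (degree and standardized Freeman
    betweenness), and identifies "key" taxonomic groups by hypergeometric
    over-representation in the top of the centrality rank, plus "dominant"
    groups by sheer share of the top set. Includes a synthetic community
    generator with planted correlated hub blocks so the whole pipeline is
    testable without external data, and a per-body-site pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
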