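Package: mitobingo
Title: Exchange of Genetic Material on Mitochondrial Encounter Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how plant mitochondria, which individually carry
    only subgenomic mitochondrial DNA molecules, can collect complete sets of
    mtDNA-encoded gene products by exchanging material when they meet.
    Builds timestamped encounter networks from particle-tracking trajectories
    (TrackMate XML or plain tables), simulates a gossip-style exchange/decay
    ("bingo") game on those networks, generates matched null-model network
    families (Erdos-Renyi, scale-free, Watts-Strogatz, cliquey, geometric,
    star), provides an agent-based physical simulator of heterogeneous
    diffusive and cytoskeletal organelle motion, and predicts exchange
    performance analytically with coupon-collector theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
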