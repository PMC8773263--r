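Package: lightgrn
Title: Light-Responsive Gene Regulatory Network Inference from Promoter
    Motif Scanning and No-Replicate RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers gene regulatory networks for light response in fungi by
    scanning gene upstream regions with transcription-factor position
    frequency matrices against a higher-order Markov background with exact
    score p-values, assembling the resulting binding sites into a directed
    genome-scale network, calling differentially expressed genes between
    two unreplicated RNA-seq libraries via simulated technical replicates
    after trimmed-mean-of-M-values normalization, extracting the
    DEG-induced light-responsive subnetwork, and nominating key regulators
    by outdegree, normalized betweenness, feed-forward-loop role census and
    greedy unique-target-coverage ranking. Includes a synthetic-data
    generator that plants motif sites encoding a known network and planted
    differentially expressed genes, so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
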