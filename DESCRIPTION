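Package: netmirror
Title: Network Mirroring for Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds a protein-based and a drug-based disease similarity
    network over a common disease set (Tanimoto similarity of binary
    association profiles), ranks diseases by the Kullback-Leibler
    divergence between their neighbour distributions in the two networks,
    finds biologically similar diseases with graph-based semi-supervised
    learning on the protein network, and repositions the similar diseases'
    drugs onto high-divergence candidate diseases. Includes a tiered,
    repeated k-fold cross-validation harness for the predictions and a
    synthetic tripartite association generator with a planted
    repositioning signal.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
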