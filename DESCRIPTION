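Package: slnpm
Title: Linear Neighborhood Propagation for lncRNA-miRNA Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts lncRNA-miRNA interactions in a bipartite network by
    learning linear neighborhood similarities from 5-mer sequence features
    and from interaction profiles, combining the two information sources with
    either a similarity-level switch (SC) or sequence-based interaction
    profile complementation (PC) so that entities without any known
    interaction remain predictable, propagating the known labels over the
    lncRNA and miRNA similarity graphs, and fusing the two propagation
    scores with a weighted average. Includes repeated cross-validated
    evaluation (AUPR, AUC, top-k recall), a parameter grid search, a
    synthetic bipartite-network generator with planted group structure for
    testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
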