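Package: synteloss
Title: Synteny-Aware Screening for Genes Lost or Emerged at an Evolutionary Stage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Calls per-species gene presence or absence from normalized
    protein homology weights and local-synteny evidence, then screens for
    genes lost (or emerged) at a chosen evolutionary stage. Pairwise local
    alignment scores are normalized to homology weights, projected to genes,
    and truncated to a per-species top-u table of homologs with ranks and
    back-ranks. A candidate ortholog must pass a forward check (witness gene
    pairs in a fixed neighborhood of both genes) and a backward check (no
    alternative homolog in the reference closer by more than a threshold
    lambda). Presence calls over configured species groups feed boolean
    metaconditions, intersection with a differential-expression table, and a
    three-species exclusion filter evaluated at several neighborhood radii.
    Includes a synthetic multi-species genome generator with planted losses,
    paralogs and synteny structure, plus an independent brute-force oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
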