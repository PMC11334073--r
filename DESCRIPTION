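Package: dtlrecon
Title: Duplication-Transfer-Loss Reconciliation and Gene-Flow Analytics for
    Virus Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parsimony-based reconciliation of gene trees with a rooted
    species tree under an undated duplication-transfer-loss (DTL) model,
    with uniform sampling of co-optimal scenarios, cost-grid sensitivity
    runs, and median aggregation over reconciliation trials. Downstream
    analytics reconstruct ancestral gene contents, split gene gains into
    origination, duplication, and virus-to-virus horizontal transfer
    (vHGT), normalize donor-recipient transfer frequencies between
    lineages, test host-range overlap effects (Mann-Whitney U with
    Cliff's delta), compute per-family transfer propensities, and relate
    event rates to relative evolutionary divergence (RED). A
    birth-and-death gene-family simulator with a ground-truth event log
    makes the whole pipeline testable on synthetic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
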