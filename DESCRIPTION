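Package: dgsa
Title: Dysfunctional Gene Set Analysis Across Methylation, MicroRNA and
    mRNA Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates tumor-versus-normal methylation, microRNA and mRNA
    profiling studies at the level of functional gene sets.  For every
    annotation term three parallel member sets are built (methylation-measured
    genes, microRNAs with annotated consensus targets, and measured mRNA
    genes), each set is scored for its ability to separate tumor from normal
    samples with a nearest-neighbor classifier under cosine distance,
    leave-one-out cross-validation and the Matthews correlation coefficient,
    and terms are ranked within levels, classified into the six possible rank
    orderings and ordered by summed rank.  Downstream utilities extract
    high-frequency members from the top dysfunctional sets, test pathway
    overlap with the hypergeometric distribution and validate marker sets in
    an independent cohort.  A synthetic-study generator with planted,
    recoverable effect sizes exercises the whole pipeline without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
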