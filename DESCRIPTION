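Package: vhhmine
Title: VHH Repertoire Mining, Generative Sequence Design and Developability Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated workflow for nanobody (VHH) hit discovery from
    multi-round display-selection NGS repertoires. Clusters sequences by
    CDR3 identity, quantifies cluster- and residue-level enrichment across
    FACS sorting rounds, trains per-cluster LSTM generative sequence models
    on concatenated CDR1-3 regions, samples and ranks new CDR combinations
    by negative log-likelihood, scores sequence-level developability
    (liability motifs, isoelectric point, hydropathy, CDR charge,
    framework human-likeness), and nominates small candidate panels for
    synthesis under reproducible selection rules. Includes a seeded
    synthetic-repertoire simulator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
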