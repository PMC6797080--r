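Package: junctures
Title: Multilevel Decision Juncture Models for Implementation Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling implementation-science systems as chains of
    decision junctures embedded in a structural causal model. Provides a
    causal DAG engine (d-separation, back-door validity, enumeration of
    minimal adjustment sets, with support for bidirected edges and a
    selection node), a canonical multilevel model of a hypothetical
    cognitive behavioural therapy (CBT) implementation system spanning
    organizations, practitioners and patients, a hierarchical simulator with
    latent-utility decision nodes and potential-outcome replay for
    sample-specific true effects, least-squares and probit average
    marginal effect estimators with cluster-robust standard errors, and a
    Monte Carlo driver that summarises relative bias of short and full
    regression specifications with empirical-standard-error confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    optparse
Config/testthat/edition: 3
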