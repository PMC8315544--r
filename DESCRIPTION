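Package: cptcoord
Title: Risk-Sensitive Coordination Games with Cumulative Prospect Theory
    and Level-k Theory of Mind
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how risk sensitivity and bounded theory of
    mind shape coordination between two agents. Implements cumulative
    prospect theory (CPT) valuation of discrete prospects with Prelec and
    original-form probability weighting, mixed and pure equilibria of
    symmetric 2x2 games under CPT (with the stag hunt as the canonical
    instance), a 16-position Markov stag-hunt environment with slip noise,
    CPT Bellman value iteration with level-k policy towers (expected
    utility theory as the identity-parameter special case), and
    stationary-distribution analyses of the policy-conditioned Markov
    chain. Results are returned as tibbles with broom-style tidiers and
    ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
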