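Package: panphen
Title: Phylogeny-Aware Pan-Genome Association with Host Fitness Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links bacterial gene presence/absence variation to a quantitative
    host-fitness phenotype measured in mono-association experiments. Implements
    a phylogeny-aware presence/absence association score that weights the
    phenotype contrast between carrier and non-carrier strains by the number of
    gene gain/loss events inferred on the strain phylogeny, together with
    permutation and tree-based null confirmation tests, strain-group fitness
    contrasts (rank tests, load-adjusted linear models, mixed-effects
    supplementation contrasts), and a synthetic-data generator that evolves
    gene content by a two-state gain/loss process and draws replicate-level
    count phenotypes, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    nlme,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools,
    jsonlite
Config/testthat/edition: 3
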