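Package: oxymet
Title: Oxygen and the Evolution of Metabolic Network Chemical Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether oxygen availability drives metabolic
    network expansion and chemical diversity while controlling for shared
    evolutionary history. Computes per-species oxic/anoxic network increase
    rates from KEGG-style reaction repertoires, compares aerobes and
    anaerobes with rank tests, ordinary linear models, and brunch-style
    phylogenetically independent contrasts for binary traits, derives
    Wilcoxon-Mann-Whitney effect sizes for chemical descriptor differences
    between oxic and anoxic metabolites, and scores whether the effect size
    of the pooled (integral) network over- or under-states the per-species
    effects via a quantile-based evaluation value. Includes a synthetic
    study generator (trees, binary trait evolution, classification lists,
    reaction repertoires, descriptor tables, protein annotations) so every
    stage of the pipeline can be exercised and calibrated without access to
    licensed databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
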