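Package: oakherb
Title: Genetic Diversity Effects on Insect Herbivory in Sapling Common Gardens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for common-garden experiments that
    relate within-species genetic diversity of tree saplings to insect
    herbivory. Simulates half-sib/full-sib sapling cohorts genotyped at
    codominant microsatellite loci; verifies maternity by Mendelian exclusion
    and screens loci for genotyping error; estimates pairwise relatedness with
    a dyadic maximum-likelihood estimator over identity-by-descent modes;
    summarises plot-level genetic diversity and relatedness; partitions the
    net effect of genetic diversity on herbivory into additive
    complementarity and selection components with one-sided t-tests and
    across-diversity ANOVA; and provides the transforms and model
    simplification scaffolding for mixed-model herbivory regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
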