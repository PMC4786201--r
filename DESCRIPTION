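Package: methylinfo
Title: Information-Thermodynamic Analysis of Cytosine DNA Methylation
Version: 0.1.0
Authors@R:
    person("methylinfo", "developers", email = "methylinfo@example.org",
           role = c("aut", "cre"))
Description: Tools for treating whole-genome bisulfite methylomes as an
    information-processing system. Computes Shannon entropy of per-cytosine
    methylation levels, the absolute information change of genomic regions
    between two states and its Landauer energy equivalent, and the
    total-variation, Kullback-Leibler and squared Hellinger divergences
    between paired methylomes. Fits Weibull and generalized-gamma null
    distributions to empirical CDFs of region-level information or
    divergence, estimates DNA persistence length from the length-dependence
    of the fitted scale parameter, calls differentially (informative)
    methylated positions and regions by signal-detection thresholds with a
    Fisher exact-test comparator, and segments the pooled binary methylation
    string into potential word frameworks whose length spectrum follows an
    exponential (Boltzmann) decay law. Includes a fully seeded synthetic
    methylome simulator and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
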