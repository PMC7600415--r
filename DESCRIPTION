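Package: caprihap
Title: Lactation Curve Modelling and Casein Haplotype Association for Dairy Goats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dairy-goat milk-recording data: validation of
    test-day records, Fleischmann-style standardization of lactation yield to
    210 days in milk, an extensible registry of lactation-curve models
    (Ali-Schaeffer, parabolic yield-density, Wood, Wilmink and others) fitted
    per lactation by multi-start damped least squares, model-selection
    criteria (RSS, MSPE, adjusted R-squared, AIC, AICc, BIC, Durbin-Watson,
    Shapiro-Francia), extraction of peak and persistency curve-shape
    parameters, casein-complex haplotype summaries (minor allele frequency,
    heterozygosity, pairwise D' and r2 linkage disequilibrium, haplotype
    grouping), and one-way analysis of variance across haplotype groups with
    frequentist F statistics, Jeffreys-Zellner-Siow Bayes factors and
    credible-interval based group effects. A synthetic herd generator with
    known ground truth supports end-to-end testing without access to raw
    milk-recording archives.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
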