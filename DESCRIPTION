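Package: phylodelta
Title: Gene-Tree Concordance Factors and the Delta Test for Ancient Introgression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Branch-wise gene and site concordance factors on a species tree,
    a normalized Delta statistic contrasting the two discordant gene-tree
    topology classes around each internal branch, a gene-tree bootstrap null
    with Z-score p-values and Dunn-Sidak family-wise correction, and a
    four-taxon follow-up design for localizing introgression. Includes a
    multispecies-coalescent gene-tree simulator with instantaneous
    introgression pulses, a JC69 sequence simulator, and a forward
    Wright-Fisher simulator with genealogy tracing for testing whether
    purifying selection distorts gene-tree topology frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
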