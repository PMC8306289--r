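Package: engraftkit
Title: Quantifying Donor Engraftment in Fecal Microbiota Transplant Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify engraftment of donor-derived bacteria after
    antibiotic conditioning and fecal microbiota transplant (FMT) in 16S
    amplicon sequence variant (ASV) count data. ASVs are classified by origin
    (donor-only, recipient-baseline-only, or shared), niche occupancy of each
    origin class is tracked through the sampling time course, and engraftment
    is tested with an exact one-sided paired Wilcoxon signed-rank test with
    Benjamini-Hochberg false discovery rate control. Supporting statistics are
    implemented from first principles: inverse Simpson diversity,
    Kruskal-Wallis, unweighted and weighted UniFrac, principal coordinates
    analysis, ANOSIM, taxonomic rollups, and PCA of short-chain fatty acid
    metabolite panels. A Dirichlet-multinomial simulator generates complete
    synthetic experiments with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
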