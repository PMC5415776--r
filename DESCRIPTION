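Package: methpanel
Title: Combinatorial Selection of DNA Methylation Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Methpanel", "Developers", email = "methpanel@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering small panels of CpG methylation biomarkers
    that discriminate between two sample classes in a paired design, such as
    subcutaneous abdominal versus omental adipose tissue assayed on the
    Illumina 450K array. Candidate sites are scored by a class-separation
    merit statistic (inter-class median difference minus the within-class
    standard deviations), filtered by an exact Wilcoxon signed-rank test,
    checked for class homogeneity via maximal cliques of a thresholded
    sample-similarity graph, and reduced to a minimal representative set by a
    red/blue dominating-set formulation. Supporting stages provide paired
    t-test differential methylation with Bonferroni control, delta-beta
    binning and two-timepoint overlap reports, Pearson screens of methylation
    change against clinical trait change, a panel separation evaluator, and a
    synthetic paired-cohort simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
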