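Package: dpmerge
Title: Directional P-Value Merging for Multi-Omics Gene Prioritisation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Combines per-gene P-values from multiple omics datasets into a
    single ranked gene list while rewarding genes whose effect directions
    agree with a user-defined constraints vector and penalising genes with
    conflicting directions. Implements Fisher's method, the empirical Brown
    method for dependent P-values, directional P-value merging (DPM), and
    directional extensions of the Stouffer and Strube methods. Includes
    ranked hypergeometric pathway enrichment on the merged list with
    per-dataset evidence attribution and enrichment-map table export, a
    synthetic P-value generator for calibration benchmarking, and readers
    and writers for GMT gene-set libraries and tab-separated score matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
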