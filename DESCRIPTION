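Package: bwasplan
Title: Scan-Time and Sample-Size Planning for Brain-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing brain-wide association studies (BWAS) that
    predict phenotypes from functional connectivity. Implements the accuracy
    scaling law relating phenotypic prediction accuracy to training sample
    size N and scan time per participant T, fits it (and a logarithmic
    total-scan-duration model) to long-form accuracy tables, converts fits
    into fraction-of-maximum-accuracy design surfaces, and optimizes study
    design under economic constraints: maximizing accuracy within a fixed
    budget, or minimizing cost for a target accuracy, with cost-inefficiency
    and savings curves and bootstrap confidence intervals for the most
    cost-effective fixed scan time. A synthetic-cohort simulator and a
    kernel/linear ridge regression prediction engine with nested
    cross-validation, split-half reliability (ICC), the Haufe transform,
    corrected resampled t-tests and Benjamini-Yekutieli FDR validate the law
    end-to-end without restricted imaging data.
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
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
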