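Package: spidertune
Title: Analysis of Virtual-Spider Feature-Tuning Preference Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial-level preference data from augmented-reality
    experiments in which participants with varying spider fear (SPQ 0-30)
    tune perceptual features of virtual spiders (hairiness, body/leg
    proportions, locomotion) to make them look dangerous or harmless.
    Implements the mean-of-the-modal-part-of-the-distribution (MMPD)
    preference summary, the incoherency index |pD + pH - 1|, Spearman
    correlation matrices with a correlation power utility, heteroskedastic
    normal regression with natural cubic spline mean and log-variance as
    functions of SPQ fitted by maximum likelihood, and centroid-linkage
    hierarchical clustering with BIC selection of 2-4 Gaussian clusters.
    Includes a seeded synthetic cohort generator emulating the study design
    (45 participants, 24 trials each) so the whole pipeline runs without
    external data.
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
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
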