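Package: stressdyn
Title: Dynamic Stress-Response Reporter Screening Analysis and DILI
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved high-content imaging of
    fluorescent stress-response reporter cell lines (oxidative stress,
    ER stress, DNA damage and inflammatory signalling) exposed to drugs
    at multiples of their peak plasma concentration (C-max).  Converts
    per-cell GFP/Hoechst/propidium-iodide feature tables into well-level
    descriptor time courses (GFP-positive fractions, IQR-fence fractions,
    cytotoxicity slopes), tests time courses against vehicle controls
    with a permutation functional ANOVA, fits four-parameter log-logistic
    concentration-response curves and extracts benchmark concentrations
    (BMC) as points of departure, clusters multi-reporter dynamics with
    mean Manhattan distances and Ward linkage, and classifies severe
    versus non-severe drug-induced liver injury (DILI) with an iterative
    feature-selection and support-vector-machine procedure.  A synthetic
    screen generator with known ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    splines,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    e1071,
    ape
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
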