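Package: oralscore
Title: Four-Biomarker Immunohistochemistry Scoring of Oral Squamous Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a semi-quantitative scoring system for assessing the
    immediate risk of oral squamous malignancy from the immunohistochemical
    staining patterns of four biomarkers (CK13, CK17, Ki-67 and laminin-5
    gamma-2). Pattern calls per marker are mapped to integer pattern scores,
    summed to a total score on a 0-11 scale, and classified against a risk
    cutoff (default 9). Also provides cohort-level summaries (pattern
    prevalence, total-score histograms, proportion at or above cutoff,
    Pearson chi-square comparisons of pattern proportions, data-driven
    cutoff selection), two-observer agreement statistics (per-marker Cohen's
    kappa and binary benign/malignant agreement), paired tumor-versus-normal
    log-expression comparison for the corresponding genes (KRT13, KRT17,
    MKI67, LAMC2), and a synthetic-data layer with deterministic fixture
    cohorts and seeded generators for cohorts, rater pairs and expression
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
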