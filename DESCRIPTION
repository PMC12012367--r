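Package: divertiphen
Title: Severity Phenotyping of Diverticular Disease from EHR Events and
    Social-Needs Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based phenotyping of diverticular disease severity from
    OMOP-style electronic health record event tables: case ascertainment by a
    diverticular diagnosis code within seven days after an abdominal CT or
    lower gastrointestinal endoscopy, and assignment to diverticulosis, mild
    diverticulitis, or operative/recurrent inpatient diverticulitis via
    inpatient admission counts and linked procedures. Includes chart-review
    concordance statistics (per-class PPV/NPV, Cohen's kappa, differential
    classification), survey scoring for social-determinants-of-health
    instruments with top-box conversion and a composite unmet-social-need
    flag, deprivation-index quintile fold enrichment, an adjusted interaction
    logistic model with bagged-tree imputation and collinearity filters, and a
    seeded synthetic EHR/survey generator with known ground truth for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
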