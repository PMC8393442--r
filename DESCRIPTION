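Package: edumort
Title: Reconstruction of Education-Specific Old-Age Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric reconstruction of education-specific death rates and
    life tables when educational attainment is unrecorded at older ages, as in
    the Danish and Swedish registers. Selects the last reliable age at which the
    unknown-education share is small, extrapolates education-specific hazard
    ratios linearly toward the national mortality level at a terminal age,
    redistributes population and deaths with unknown education through a
    delta-scaled recursion solved so that unknown deaths are exhausted, and
    builds abridged and complete period life tables per education group.
    Includes a synthetic register generator emulating the cohort-driven
    missingness structure of Nordic education registers, so every stage of the
    pipeline can be exercised and validated without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
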