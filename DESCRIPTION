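Package: smallbh
Title: Under-5 Mortality Estimation from Small Birth-History Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Direct estimation of under-5 mortality (5q0) from complete
    birth histories, including the standard period-based estimator built on
    child-month expansion and synthetic-cohort life-table logic, and a
    moving-window variant with flat or triangle kernel weights that pools
    information across calendar time. Ships a demographic microsimulation
    generator of DHS-like surveys with analytically known true 5q0, and a
    resampling validation engine that subsamples women, matches estimates
    to an interpolated full-sample truth series, and summarises four error
    metrics overall and stratified by mortality level, time prior to
    survey, or number of pooled surveys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
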