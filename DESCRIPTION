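Package: fissionsizer
Title: Titration Sizer Model and Quantitative Immunofluorescence for
    Multiple Fission Cell Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models mitotic division counting in multiple fission cell
    cycles, as in the green alga Chlamydomonas reinhardtii, where a
    limiting nuclear regulator (CDKG1) is produced in proportion to
    mother cell size and is diluted and degraded with each round of
    division until it falls below an exit threshold.  Provides the
    titration model itself (allometric production, per-round dilution
    and degradation, threshold-triggered exit, and a discrete
    unit-accounting variant), a diurnal population simulator with
    dark-shift experiment designs, a quantitative immunofluorescence
    pipeline (DAPI-based nuclear segmentation, per-nucleus intensity
    and concentration, stage grouping, per-DNA ratios, rank-sum and
    ANOVA statistics), geometric volume conversions, and synthetic
    data generators with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage,
    igraph
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
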